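# Pipeline orchestration: classify -> sort -> Sigma-dN/ratios -> empirical
# null -> ML fits -> per-branch dN -> stability, from one configuration.

#' Default pipeline configuration
#'
#' Returns the configuration skeleton consumed by [run_pipeline()]. Paths
#' must be filled in (or produced by [synth_pipeline_inputs()]).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    structure = NULL,          # PDB path
    encoding = NULL,           # named list chain -> "mt"/"nuclear"
    alignments = NULL,         # named list mt chain -> FASTA path
    tree = NULL,               # Newick path
    ddg = NULL,                # optional TSV path
    ref_taxon = NULL,
    first_residue_number = 1L,
    code = "vertebrate_mito",
    contact_cutoff = 4.0,
    exposure_threshold = 0.05,
    sphere_points = 960,
    probe_radius = 1.4,
    method = "yn00",
    boot_reps = 200,
    null_B = 10000L,
    split_interface = FALSE,
    fit_branch_lengths = TRUE,
    run_lrt = FALSE,
    seed = 1L,
    out_dir = NULL
  )
}

read_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  base <- default_config()
  base[names(cfg)] <- cfg
  base
}

#' Run the full structure-conditioned evolutionary analysis
#'
#' Executes, in order: residue classification, codon sorting, Sigma-dN and
#' interaction ratios, the codon-resampling empirical null for the exposed
#' noncontact class, codon-model fits (M0 branch lengths, fixed-sites
#' partition omegas, optional M1a/M2a LRT), per-branch dN apportioning for
#' the two contact classes, and (when a stability table is configured) the
#' class-wise stability statistics and Sigma-dN correlation. Every stage's
#' outputs are written under `out_dir` as TSV/JSON, the configuration is
#' serialised alongside them, and a failure stops with the failing stage
#' named (partial outputs are retained).
#'
#' @param cfg Configuration list (see [default_config()]) or a YAML path.
#' @return Invisibly, a `pipeline_report` list with per-stage results.
#' @export
run_pipeline <- function(cfg) {
  cfg <- read_config(cfg)
  if (is.null(cfg$out_dir)) stop("config needs an out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))
  logf <- file.path(cfg$out_dir, "pipeline.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    cat(line, "\n", file = logf, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, " start")
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logmsg("stage ", name, " done")
    out
  }
  report <- list(config = cfg)
  for (p in c(cfg$structure, cfg$tree, unlist(cfg$alignments), cfg$ddg)) {
    if (!is.null(p) && !file.exists(p)) stop("input file missing: ", p)
  }
  encoding <- unlist(cfg$encoding)
  mt_chains <- names(encoding)[encoding == "mt"]

  # --- structural classification -------------------------------------------
  labels <- stage("classify", {
    cx <- parse_structure(cfg$structure, encoding)
    partners <- build_contact_labels(cx, cutoff = cfg$contact_cutoff)
    asa2 <- compute_residue_asa(cx, probe_radius = cfg$probe_radius,
                                sphere_points = cfg$sphere_points)
    asa1 <- unlist(lapply(names(encoding), function(ch)
      compute_residue_asa(cx, chains = ch, probe_radius = cfg$probe_radius,
                          sphere_points = cfg$sphere_points)))
    lab <- classify_sites(cx, asa1, asa2, partners, chains = mt_chains,
                          exposure_threshold = cfg$exposure_threshold)
    hd <- if (any(cx$hetero$is_heme)) {
      unlist(lapply(mt_chains, function(ch) heme_min_distances(cx, ch)))
    } else NULL
    write_labels_tsv(lab, file.path(cfg$out_dir, "site_labels.tsv"),
                     heme_dist = hd)
    report$structure <- cx
    report$heme_dist <- hd
    lab
  })
  report$labels <- labels

  # --- codon sorting --------------------------------------------------------
  parts <- stage("sort", {
    out <- list()
    for (ch in names(cfg$alignments)) {
      aln <- read_codon_alignment(cfg$alignments[[ch]], code = cfg$code)
      offs <- if (length(cfg$first_residue_number) > 1)
        cfg$first_residue_number[[ch]] else cfg$first_residue_number
      rmap <- map_alignment_to_reference(aln, cfg$ref_taxon, ch,
                                         first_residue_number = offs)
      part <- partition_alignment(aln, rmap, labels,
                                  split_interface = cfg$split_interface)
      write_partition_tsv(part, file.path(cfg$out_dir,
                                          paste0("partition_", ch, ".tsv")))
      for (cl in names(part$alignments)) {
        if (!is.null(part$alignments[[cl]]))
          write_codon_alignment(part$alignments[[cl]],
                                file.path(cfg$out_dir,
                                          paste0("class_", ch, "_", cl,
                                                 ".fasta")))
      }
      out[[ch]] <- list(aln = aln, refmap = rmap, partition = part)
    }
    out
  })

  # --- Sigma-dN and interaction ratios -------------------------------------
  divg <- stage("sumdn", {
    res <- list()
    for (ch in names(parts)) {
      sub <- parts[[ch]]$partition$alignments
      sums <- lapply(sub, function(a)
        if (!is.null(a)) sum_dn(a, method = cfg$method,
                                boot_reps = cfg$boot_reps,
                                seed = cfg$seed + 11L) else NULL)
      ratios <- list()
      if (!is.null(sums$MT_NU_CONTACT) && !is.null(sums$EXPOSED_NONCONTACT))
        ratios$mtnu_vs_exposed <-
          interaction_ratio(sums$MT_NU_CONTACT, sums$EXPOSED_NONCONTACT)
      if (!is.null(sums$MT_MT_CONTACT) && !is.null(sums$EXPOSED_NONCONTACT))
        ratios$mtmt_vs_exposed <-
          interaction_ratio(sums$MT_MT_CONTACT, sums$EXPOSED_NONCONTACT)
      res[[ch]] <- list(sums = sums, ratios = ratios)
    }
    json <- lapply(res, function(r) list(
      sum_dn = lapply(r$sums, function(s)
        if (is.null(s)) NULL else
          list(sum_dn = s$sum_dn, n_pairs = s$n_pairs, se = s$se_sum_dn)),
      ratios = lapply(r$ratios, function(x) x$ratio)))
    jsonlite::write_json(json, file.path(cfg$out_dir, "sumdn.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    res
  })
  report$divergence <- divg

  # --- empirical null for the exposed noncontact class ----------------------
  nulls <- stage("nullboot", {
    res <- list()
    for (ch in names(parts)) {
      part <- parts[[ch]]$partition
      cols <- part$classes$EXPOSED_NONCONTACT
      if (is.null(cols) || length(cols) < 1) next
      aln <- parts[[ch]]$aln
      nd <- sample_null_sumdn(aln, m = length(cols), B = cfg$null_B,
                              seed = cfg$seed + 23L, method = cfg$method)
      obs <- divg[[ch]]$sums$EXPOSED_NONCONTACT$sum_dn
      res[[ch]] <- list(observed = obs, m = nd$m, B = nd$B,
                        p_lower = empirical_pvalue(obs, nd, "lower"),
                        p_upper = empirical_pvalue(obs, nd, "upper"))
      write.table(data.frame(sum_dn = nd$values),
                  file.path(cfg$out_dir, paste0("null_", ch, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(res, file.path(cfg$out_dir, "null_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })
  report$null_tests <- nulls

  # --- codon-model fits -----------------------------------------------------
  ml <- stage("ml", {
    tree <- ape::read.tree(cfg$tree)
    res <- list()
    for (ch in names(parts)) {
      aln <- parts[[ch]]$aln
      part <- parts[[ch]]$partition
      tr <- tree
      if (!setequal(tr$tip.label, aln$taxa))
        tr <- ape::keep.tip(tr, intersect(tr$tip.label, aln$taxa))
      m0 <- if (cfg$fit_branch_lengths) fit_m0(tr, aln) else
        list(tree = tr, kappa = 2, omega = NA)
      fs <- fit_fixed_sites(m0$tree, part$alignments)
      bdn <- NULL
      if (!is.null(part$alignments$MT_NU_CONTACT) &&
          !is.null(part$alignments$MT_MT_CONTACT)) {
        bdn <- branch_dn(m0$tree, part$alignments, fs$omegas, fs$kappa,
                         contrast = c("MT_NU_CONTACT", "MT_MT_CONTACT"))
        write_branch_dn_tsv(bdn, file.path(cfg$out_dir,
                                           paste0("branch_dn_", ch, ".tsv")))
      }
      lrt <- if (isTRUE(cfg$run_lrt)) fit_site_models_lrt(m0$tree, aln) else
        NULL
      ape::write.tree(m0$tree, file.path(cfg$out_dir,
                                         paste0("tree_m0_", ch, ".nwk")))
      res[[ch]] <- list(m0 = m0, fixed_sites = fs, branch_dn = bdn,
                        lrt = lrt)
    }
    omtab <- do.call(rbind, lapply(names(res), function(ch) {
      fs <- res[[ch]]$fixed_sites
      data.frame(chain = ch, class = names(fs$omegas),
                 omega = unname(fs$omegas), se = unname(fs$se_omegas),
                 kappa = fs$kappa, lnL = fs$lnL)
    }))
    write.table(omtab, file.path(cfg$out_dir, "omega_by_class.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  report$ml <- ml

  # --- stability ------------------------------------------------------------
  if (is.null(cfg$ddg)) {
    logmsg("stage stability skipped: no ddg table configured")
  } else {
    report$stability <- stage("stability", {
      ddg <- read_ddg_tsv(cfg$ddg)
      gs <- group_ddg_stats(ddg, labels)
      write.table(gs$stats, file.path(cfg$out_dir, "ddg_stats.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(gs$contrasts, file.path(cfg$out_dir, "ddg_contrasts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      # per-subunit (contact, exposed-noncontact) points for the
      # Sigma-dN vs stability correlation
      pts <- list()
      for (ch in names(divg)) {
        sums <- divg[[ch]]$sums
        part <- parts[[ch]]$partition
        m <- merge(ddg, labels[, c("chain", "resno", "site_class")],
                   by = c("chain", "resno"))
        m <- m[m$chain == ch, ]
        con <- m$site_class %in% c("MT_NU_CONTACT", "MT_MT_CONTACT")
        expn <- m$site_class == "EXPOSED_NONCONTACT"
        sdn_con <- sum(vapply(c("MT_NU_CONTACT", "MT_MT_CONTACT"),
                              function(cl)
                                if (is.null(sums[[cl]])) 0 else
                                  sums[[cl]]$sum_dn, numeric(1)))
        if (any(con) && !is.null(sdn_con))
          pts[[length(pts) + 1L]] <- data.frame(
            label = paste0(ch, "_Contact"), sum_dn = sdn_con,
            mean_ddg = mean(m$ddg_kj_mol[con]))
        if (any(expn) && !is.null(sums$EXPOSED_NONCONTACT))
          pts[[length(pts) + 1L]] <- data.frame(
            label = paste0(ch, "_ExposedNoncontact"),
            sum_dn = sums$EXPOSED_NONCONTACT$sum_dn,
            mean_ddg = mean(m$ddg_kj_mol[expn]))
      }
      pts <- do.call(rbind, pts)
      corr <- if (!is.null(pts) && nrow(pts) >= 3) dn_ddg_correlation(pts)
        else NULL
      jsonlite::write_json(
        list(n = corr$n, r = corr$r, p = corr$p),
        file.path(cfg$out_dir, "ddg_correlation.json"),
        auto_unbox = TRUE, digits = NA)
      list(stats = gs, points = pts, correlation = corr)
    })
  }

  # --- plain-text summary ---------------------------------------------------
  summ <- file.path(cfg$out_dir, "summary.txt")
  lines <- c("structure-conditioned evolutionary analysis", "")
  for (ch in names(divg)) {
    lines <- c(lines, paste0("chain ", ch, ":"))
    for (cl in names(divg[[ch]]$sums)) {
      s <- divg[[ch]]$sums[[cl]]
      if (!is.null(s))
        lines <- c(lines, sprintf("  sum dN %-22s %10.4f (%d pairs)",
                                  cl, s$sum_dn, s$n_pairs))
    }
    for (rn in names(divg[[ch]]$ratios))
      lines <- c(lines, sprintf("  ratio %-23s %10.4f", rn,
                                divg[[ch]]$ratios[[rn]]$ratio))
    fs <- ml[[ch]]$fixed_sites
    for (cl in names(fs$omegas))
      if (is.finite(fs$omegas[[cl]]))
        lines <- c(lines, sprintf("  omega %-23s %10.4f", cl,
                                  fs$omegas[[cl]]))
    if (!is.null(nulls[[ch]]))
      lines <- c(lines, sprintf("  exposed-noncontact null p: lower %.4g upper %.4g",
                                nulls[[ch]]$p_lower, nulls[[ch]]$p_upper))
  }
  writeLines(lines, summ)
  logmsg("pipeline complete")
  class(report) <- "pipeline_report"
  invisible(report)
}

#' Generate a complete synthetic input bundle for the pipeline
#'
#' Builds a toy complex with planted classes, a random tree, codon
#' alignments whose columns carry class-specific omegas matched to the
#' planted residue classes of each mt chain, and a stability table with
#' class-dependent means; writes everything under `dir` in the standard
#' formats (PDB, FASTA, Newick, TSV) and returns a ready-to-run
#' configuration.
#'
#' The default class omegas encode the biological expectations the analysis
#' is designed to detect: intra-genome contacts most constrained, buried
#' residues constrained, inter-genome contacts intermediate, exposed
#' noncontact residues least constrained.
#'
#' @param dir Output directory for the generated inputs.
#' @param preset `"small"` (2 mt + 2 nuclear chains, 8 taxa) or
#'   `"paperlike"` (3 mt + 10 nuclear chains, 24 taxa).
#' @param seed RNG seed controlling every random stage.
#' @param class_omegas Named vector of omegas per structural class.
#' @param kappa Transition/transversion ratio for simulation.
#' @param mean_branch_length Mean branch length (substitutions/codon).
#' @return List with `config` (for [run_pipeline()]), `truth` (planted
#'   classes and simulation parameters).
#' @export
synth_pipeline_inputs <- function(dir, preset = c("small", "paperlike"),
                                  seed = 1L,
                                  class_omegas = c(MT_NU_CONTACT = 0.3,
                                                   MT_MT_CONTACT = 0.05,
                                                   EXPOSED_NONCONTACT = 0.6,
                                                   BURIED_NONCONTACT = 0.1),
                                  kappa = 4,
                                  mean_branch_length = 0.08) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pp <- if (preset == "small")
    list(n_chains = 4, n_mt = 2, rpc = 30, taxa = 8) else
    list(n_chains = 13, n_mt = 3, rpc = 40, taxa = 24)
  toy <- make_toy_complex(n_chains = pp$n_chains,
                          residues_per_chain = pp$rpc,
                          contact_fraction = 0.25, buried_fraction = 0.15,
                          interface_fraction = 0.1, n_mt = pp$n_mt,
                          seed = seed)
  pdb <- file.path(dir, "complex.pdb")
  writeLines(toy$pdb_lines, pdb)
  tree <- simulate_tree(pp$taxa, mean_branch_length, seed = seed + 1L)
  nwk <- file.path(dir, "tree.nwk")
  ape::write.tree(tree, nwk)
  mt_chains <- names(toy$encoding)[toy$encoding == "mt"]
  aln_paths <- list()
  for (i in seq_along(mt_chains)) {
    ch <- mt_chains[i]
    # planted class of strand residues 1..rpc, in residue order
    tr <- toy$truth[toy$truth$chain == ch & toy$truth$resno <= pp$rpc, ]
    tr <- tr[order(tr$resno), ]
    cls <- tr$class
    counts <- table(factor(cls, levels = names(class_omegas)))
    sim <- simulate_codon_alignment(
      tree, class_omegas,
      cols_per_partition = setNames(as.integer(counts), names(class_omegas)),
      kappa = kappa, seed = seed + 100L + i)
    # reorder the block-simulated columns so column r carries the class of
    # residue r
    ord <- order(order(match(cls, names(class_omegas))))
    aln <- subset_alignment(sim$alignment, ord)
    p <- file.path(dir, paste0("aln_", ch, ".fasta"))
    write_codon_alignment(aln, p)
    aln_paths[[ch]] <- p
  }
  ddg_params <- list(MT_NU_CONTACT = c(2.0, 1.6), MT_MT_CONTACT = c(1.8, 1.6),
                     EXPOSED_NONCONTACT = c(1.3, 1.4),
                     BURIED_NONCONTACT = c(3.0, 2.0))
  ddg <- simulate_ddg_table(toy$truth, ddg_params, seed = seed + 7L)
  ddg_path <- file.path(dir, "ddg.tsv")
  write.table(ddg, ddg_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- default_config()
  cfg$structure <- pdb
  cfg$encoding <- as.list(toy$encoding)
  cfg$alignments <- aln_paths
  cfg$tree <- nwk
  cfg$ddg <- ddg_path
  cfg$ref_taxon <- "t1"
  cfg$seed <- seed
  cfg$null_B <- 999L
  cfg$boot_reps <- 100
  list(config = cfg,
       truth = list(toy = toy, class_omegas = class_omegas, kappa = kappa,
                    tree = tree, preset = preset, seed = seed))
}
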