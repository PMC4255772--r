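# Synthetic inputs with planted ground truth: toy complexes, random trees,
# codon alignments under partition-specific omega, stability tables.

#' Generate a toy multi-chain complex with planted structural classes
#'
#' Chains are laid out as straight strands of single-heavy-atom (glycine
#' like) residues on parallel lines 40 A apart, spaced 9 A along the
#' strand so that no unintended inter-chain contact or surface shadowing
#' arises. Planted features:
#' * contact residues are moved into a chain-specific "bridge lane"
#'   together with a partner residue appended to the designated target
#'   chain, the pair exactly 3.5 A apart (under the 4 A rule they, and
#'   only they, are inter-chain contacts);
#' * buried residues are enclosed by a 12-atom icosahedral shell (radius
#'   3 A) carried by a same-chain scaffold residue, driving their
#'   accessible area to zero;
#' * interface residues (optional) are paired 5.5 A from a partner residue
#'   of another chain in a separate lane: no atomic contact, but close
#'   enough that complexation reduces their accessible area (delta-ASA
#'   > 0);
#' * a pseudo-heme hetero group is placed at a fixed offset from chain 1.
#'
#' The first `n_mt` chains are flagged mtDNA-encoded, the rest nuclear.
#' Contacts are planted alternately against a nuclear and (when `n_mt >=
#' 2`) another mt chain, so both contact classes occur. The `truth` table
#' records the planted class of every residue of every mt chain (including
#' scaffold and partner residues), which the structural classifier is
#' expected to recover exactly.
#'
#' @param n_chains Number of chains (>= 2).
#' @param residues_per_chain Strand residues per chain.
#' @param contact_fraction Fraction of each mt chain's strand residues
#'   planted as contacts.
#' @param buried_fraction Fraction planted as buried.
#' @param interface_fraction Fraction planted as exposed interface
#'   (noncontact, delta-ASA > 0).
#' @param n_mt Number of mtDNA-encoded chains.
#' @param seed RNG seed; the layout is reproducible.
#' @return List with `structure` (a `complex_structure`), `truth` (data
#'   frame: chain, resno, class, interface, key), `encoding`, `pdb_lines`
#'   (PDB text of the complex) and `params`.
#' @export
make_toy_complex <- function(n_chains = 4, residues_per_chain = 20,
                             contact_fraction = 0.2, buried_fraction = 0.2,
                             interface_fraction = 0.1, n_mt = 2, seed = 7) {
  stopifnot(n_chains >= 2, n_mt >= 1, n_mt < n_chains)
  if (contact_fraction < 0 || buried_fraction < 0 || interface_fraction < 0 ||
      contact_fraction + buried_fraction + interface_fraction > 1)
    stop("class fractions must be nonnegative and sum to <= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  chain_ids <- LETTERS[seq_len(n_chains)]
  encoding <- setNames(c(rep("mt", n_mt), rep("nuclear", n_chains - n_mt)),
                       chain_ids)
  spacing <- 9
  chain_gap <- 40
  # icosahedral directions for the burial shell
  ico <- rbind(c(0, 0, 1), c(0, 0, -1),
               t(vapply(0:4, function(k) {
                 th <- 2 * pi * k / 5
                 c(cos(th) * 2 / sqrt(5), sin(th) * 2 / sqrt(5), 1 / sqrt(5))
               }, numeric(3))),
               t(vapply(0:4, function(k) {
                 th <- 2 * pi * (k + 0.5) / 5
                 c(cos(th) * 2 / sqrt(5), sin(th) * 2 / sqrt(5), -1 / sqrt(5))
               }, numeric(3))))
  n_contact <- round(contact_fraction * residues_per_chain)
  n_buried <- round(buried_fraction * residues_per_chain)
  n_iface <- round(interface_fraction * residues_per_chain)
  rows <- list(); truth <- list()
  atom_serial <- 0L
  add_atom <- function(chain, resno, x, y, z, resid = "GLY", elety = "CA") {
    atom_serial <<- atom_serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      type = "ATOM", eleno = atom_serial, elety = elety, resid = resid,
      chain = chain, resno = resno, x = x, y = y, z = z,
      stringsAsFactors = FALSE)
  }
  add_truth <- function(chain, resno, class, interface = NA) {
    truth[[length(truth) + 1L]] <<- data.frame(
      chain = chain, resno = resno, class = class, interface = interface,
      stringsAsFactors = FALSE)
  }
  for (ci in seq_len(n_mt)) {
    ch <- chain_ids[ci]
    y0 <- (ci - 1) * chain_gap
    zc <- 10 + 8 * (ci - 1)   # contact-bridge lane for this chain
    zi <- 60 + 8 * (ci - 1)   # interface-pair lane for this chain
    roles <- rep("EXPOSED_NONCONTACT", residues_per_chain)
    n_special <- min(residues_per_chain, n_contact + n_buried + n_iface)
    pick <- sample.int(residues_per_chain, n_special)
    if (n_contact > 0) roles[pick[seq_len(n_contact)]] <- "CONTACT"
    if (n_buried > 0)
      roles[pick[n_contact + seq_len(n_buried)]] <- "BURIED_NONCONTACT"
    if (n_iface > 0)
      roles[pick[n_contact + n_buried + seq_len(n_iface)]] <- "IFACE"
    others <- setdiff(seq_len(n_chains), ci)
    nuc <- others[encoding[chain_ids[others]] == "nuclear"]
    mts <- others[encoding[chain_ids[others]] == "mt"]
    contact_no <- 0L
    for (r in seq_len(residues_per_chain)) {
      x <- (r - 1) * spacing
      role <- roles[r]
      if (role == "CONTACT") {
        contact_no <- contact_no + 1L
        pool <- if (contact_no %% 2 == 1 && length(nuc)) nuc else
          if (length(mts)) mts else nuc
        tci <- pool[1 + (contact_no %/% 2) %% length(pool)]
        tch <- chain_ids[tci]
        ymid <- (y0 + (tci - 1) * chain_gap) / 2
        add_atom(ch, r, x, ymid - 1.75, zc)
        pr <- 1000L + atom_serial
        add_atom(tch, pr, x, ymid + 1.75, zc)
        cls <- if (encoding[tch] == "nuclear") "MT_NU_CONTACT" else
          "MT_MT_CONTACT"
        add_truth(ch, r, cls)
        if (encoding[tch] == "mt") add_truth(tch, pr, "MT_MT_CONTACT")
      } else if (role == "BURIED_NONCONTACT") {
        add_atom(ch, r, x, y0, 0)
        scaf <- 3000L + atom_serial
        for (s in seq_len(nrow(ico)))
          add_atom(ch, scaf, x + 3 * ico[s, 1], y0 + 3 * ico[s, 2],
                   3 * ico[s, 3], elety = paste0("C", s))
        add_truth(ch, r, "BURIED_NONCONTACT")
        add_truth(ch, scaf, "EXPOSED_NONCONTACT", interface = FALSE)
      } else if (role == "IFACE") {
        tci <- if (length(nuc)) nuc[1] else mts[1]
        tch <- chain_ids[tci]
        ymid <- (y0 + (tci - 1) * chain_gap) / 2
        add_atom(ch, r, x, ymid - 2.75, zi)
        pr <- 2000L + atom_serial
        add_atom(tch, pr, x, ymid + 2.75, zi)
        add_truth(ch, r, "EXPOSED_NONCONTACT", interface = TRUE)
        if (encoding[tch] == "mt")
          add_truth(tch, pr, "EXPOSED_NONCONTACT", interface = TRUE)
      } else {
        add_atom(ch, r, x, y0, 0)
        add_truth(ch, r, "EXPOSED_NONCONTACT", interface = FALSE)
      }
    }
  }
  # nuclear chains: plain strands (partner residues were appended above)
  for (ci in setdiff(seq_len(n_chains), seq_len(n_mt))) {
    ch <- chain_ids[ci]
    y0 <- (ci - 1) * chain_gap
    for (r in seq_len(residues_per_chain))
      add_atom(ch, r, (r - 1) * spacing, y0, 0)
  }
  at <- do.call(rbind, rows)
  hem <- data.frame(type = "HETATM", eleno = max(at$eleno) + 1:4,
                    elety = c("FE", "C1", "C2", "C3"), resid = "HEM",
                    chain = chain_ids[1], resno = 9001L,
                    x = c(0, 2, -2, 0), y = -15, z = c(0, 0, 0, 2),
                    stringsAsFactors = FALSE)
  at <- rbind(at, hem)
  pdb_path <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = at$type, resno = at$resno, resid = at$resid,
                   eleno = at$eleno, elety = at$elety, chain = at$chain,
                   elesy = substr(at$elety, 1, 1))
  cx <- parse_structure(pdb_path, encoding)
  pdb_lines <- readLines(pdb_path)
  unlink(pdb_path)
  tr <- do.call(rbind, truth)
  tr$key <- res_key(tr$chain, tr$resno, "")
  list(structure = cx, truth = tr, encoding = encoding,
       pdb_lines = pdb_lines,
       params = list(n_chains = n_chains,
                     residues_per_chain = residues_per_chain,
                     contact_fraction = contact_fraction,
                     buried_fraction = buried_fraction,
                     interface_fraction = interface_fraction,
                     n_mt = n_mt, seed = seed))
}

#' Simulate a random unrooted binary tree
#'
#' Random topology with i.i.d. exponential branch lengths; an unrooted
#' binary tree over n tips has 2n - 3 branches.
#'
#' @param n_tips Number of tips (>= 3).
#' @param mean_branch_length Mean of the exponential branch lengths
#'   (expected nucleotide substitutions per codon).
#' @param seed RNG seed.
#' @return An unrooted `ape::phylo` with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_tips, mean_branch_length = 0.1, seed = 1L) {
  stopifnot(n_tips >= 3)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_tips, rooted = TRUE, br = NULL))
  tr$edge.length <- rexp(nrow(tr$edge), rate = 1 / mean_branch_length)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

#' Simulate a codon alignment under partition-specific omega
#'
#' Root codons are drawn from the stationary distribution pi; each branch
#' evolves states by exact sampling from exp(Qt) with the column's
#' partition omega (per-column independence, GY94 dynamics, no stop codons
#' by construction of the state space).
#'
#' @param tree `ape::phylo` with branch lengths in substitutions per codon.
#' @param omega_map Named numeric vector: partition name -> omega.
#' @param cols_per_partition Named integer vector (same names): columns to
#'   simulate per partition, emitted in partition order.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (default: uniform over sense codons).
#' @param code Genetic code name.
#' @param seed RNG seed.
#' @param scale `"per_partition"` (default): each partition's generator is
#'   normalised to one substitution per codon, so partitions differ only in
#'   the synonymous/nonsynonymous composition of change (the convention of
#'   the fixed-sites fit); `"common"`: one scale shared across partitions
#'   weighted by their column fractions, so high-omega partitions evolve
#'   genuinely faster (the convention of the mixture site models).
#' @return List with `alignment` (a `codon_alignment`), `partition` (factor
#'   of partition names per column), `truth` (the generating parameters).
#' @export
simulate_codon_alignment <- function(tree, omega_map, cols_per_partition,
                                     kappa = 4, pi = NULL,
                                     code = "vertebrate_mito", seed = 1L,
                                     scale = c("per_partition", "common")) {
  stopifnot(setequal(names(omega_map), names(cols_per_partition)))
  scale <- match.arg(scale)
  gc <- genetic_code(code)
  if (is.null(pi)) pi <- setNames(rep(1 / gc$n_state, gc$n_state), gc$sense)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  common_scale <- if (scale == "common") {
    fr <- cols_per_partition[names(omega_map)] /
      sum(cols_per_partition)
    sum(fr * vapply(omega_map, function(om)
      gy94_mean_rate(pi, kappa, om, code), numeric(1)))
  } else NULL
  tr <- ape::reorder.phylo(tree, "cladewise")  # parent before child
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  blocks <- list(); partcol <- character(0)
  for (pname in names(omega_map)) {
    ncols <- cols_per_partition[[pname]]
    if (ncols == 0L) next
    eg <- codon_eigen(pi, kappa, omega_map[[pname]], code,
                      scale_factor = common_scale)
    nnode <- ntip + tr$Nnode
    states <- matrix(NA_integer_, nnode, ncols)
    states[root, ] <- sample.int(gc$n_state, ncols, replace = TRUE,
                                 prob = eg$pi)
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      P <- prob_matrix(eg, max(tr$edge.length[e], 0))
      ps <- states[parent, ]
      cs <- integer(ncols)
      for (s in unique(ps)) {
        idx <- which(ps == s)
        pr <- pmax(P[s, ], 0)
        cs[idx] <- sample.int(gc$n_state, length(idx), replace = TRUE,
                              prob = pr / sum(pr))
      }
      states[child, ] <- cs
    }
    blocks[[pname]] <- states[seq_len(ntip), , drop = FALSE]
    partcol <- c(partcol, rep(pname, ncols))
  }
  allstates <- do.call(cbind, blocks)
  codons <- matrix(gc$sense[allstates], nrow = ntip,
                   dimnames = list(tr$tip.label, NULL))
  aln <- codon_alignment(codons, code = code)
  list(alignment = aln,
       partition = factor(partcol, levels = names(omega_map)),
       truth = list(omega_map = omega_map, kappa = kappa, pi = pi,
                    seed = seed, tree = tree))
}

#' Simulate a per-residue stability-change table with class-dependent means
#'
#' Stands in for an external alanine-scan: each residue's delta-delta-G is
#' drawn from a normal distribution whose mean and standard deviation
#' depend on its structural class.
#'
#' @param labels A `site_labels` data frame (or the `truth` table of
#'   [make_toy_complex()] with a `class` column).
#' @param class_params Named list: class -> c(mean, sd) in kJ/mol.
#' @param seed RNG seed.
#' @return Data frame (`ddg_table`): chain, resno, ddg_kj_mol.
#' @export
simulate_ddg_table <- function(labels, class_params, seed = 1L) {
  cls <- if ("site_class" %in% names(labels)) labels$site_class else
    labels$class
  missing <- setdiff(unique(cls), names(class_params))
  if (length(missing))
    stop("no delta-delta-G parameters for class: ",
         paste(missing, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mu <- vapply(class_params[cls], `[`, numeric(1), 1)
  sg <- vapply(class_params[cls], `[`, numeric(1), 2)
  out <- data.frame(chain = labels$chain, resno = labels$resno,
                    ddg_kj_mol = rnorm(length(cls), mu, sg),
                    stringsAsFactors = FALSE)
  class(out) <- c("ddg_table", "data.frame")
  out
}
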