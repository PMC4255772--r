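#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim nlminb pchisq pt qt sd t.test ks.test cor.test
#'   runif rexp rnorm setNames aggregate
#' @importFrom utils write.table read.table combn head tail
NULL

# Cache for per-code codon machinery (tables are deterministic, built once).
.ifacevol_cache <- new.env(parent = emptyenv())

NUC <- c("A", "C", "G", "T")

#' Genetic code machinery for codon-level analyses
#'
#' Builds (and caches) the codon state space for a genetic code: the list of
#' sense codons, the amino acid translation, and the transition/transversion
#' structure of all single-nucleotide codon changes. The vertebrate
#' mitochondrial code (60 sense codons; stops TAA, TAG, AGA, AGG) is the
#' default throughout the package because the motivating analyses concern
#' mtDNA-encoded genes; the universal code (61 sense codons) is also
#' supported.
#'
#' @param code Either `"vertebrate_mito"` (NCBI translation table 2) or
#'   `"universal"` (table 1).
#' @return A list with elements `name`, `codons` (all 64), `aa` (named
#'   translation vector, `"*"` for stops), `sense` (sense codons in fixed
#'   order), `n_state` (number of sense codons), and `stops`.
#' @export
genetic_code <- function(code = c("vertebrate_mito", "universal")) {
  code <- match.arg(code)
  key <- paste0("code_", code)
  if (!is.null(.ifacevol_cache[[key]])) return(.ifacevol_cache[[key]])
  id <- if (code == "vertebrate_mito") "2" else "1"
  tab <- Biostrings::getGeneticCode(id)
  codons <- names(tab)
  sense <- codons[tab != "*"]
  out <- list(
    name = code,
    codons = codons,
    aa = tab,
    sense = sense,
    n_state = length(sense),
    stops = codons[tab == "*"]
  )
  .ifacevol_cache[[key]] <- out
  out
}

#' Translate a vector of codons
#'
#' @param codons Character vector of 3-letter codons.
#' @param code Genetic code name (see [genetic_code()]).
#' @return Character vector of one-letter amino acids (`"*"` for stops, `NA`
#'   for codons containing gaps or ambiguity characters).
#' @export
translate_codons <- function(codons, code = "vertebrate_mito") {
  gc <- genetic_code(code)
  out <- unname(gc$aa[codons])
  out
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# Enumerate single-nucleotide neighbours of a codon; returns a data.frame
# with position, target codon, transition flag.
codon_neighbours <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  res <- vector("list", 9L)
  k <- 0L
  for (pos in 1:3) {
    for (alt in setdiff(NUC, nts[pos])) {
      k <- k + 1L
      new <- nts
      new[pos] <- alt
      res[[k]] <- data.frame(
        pos = pos, to = paste(new, collapse = ""),
        ts = is_transition(nts[pos], alt), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}

# Per-codon, per-position counts of synonymous / nonsynonymous / stop
# single-nucleotide changes, split by transition vs transversion.  Used for
# mutational-opportunity site counting (Nei-Gojobori style, optionally
# weighted by a transition/transversion ratio kappa).
codon_site_profile <- function(code) {
  gc <- genetic_code(code)
  key <- paste0("siteprof_", code)
  if (!is.null(.ifacevol_cache[[key]])) return(.ifacevol_cache[[key]])
  prof <- array(0L, dim = c(length(gc$sense), 3L, 4L),
                dimnames = list(gc$sense, NULL,
                                c("syn_ts", "syn_tv", "non_ts", "non_tv")))
  for (c1 in gc$sense) {
    nb <- codon_neighbours(c1)
    aa1 <- gc$aa[[c1]]
    for (i in seq_len(nrow(nb))) {
      aa2 <- gc$aa[[nb$to[i]]]
      if (aa2 == "*") next  # changes to stop codons are not counted as sites
      slot <- if (aa2 == aa1) {
        if (nb$ts[i]) "syn_ts" else "syn_tv"
      } else {
        if (nb$ts[i]) "non_ts" else "non_tv"
      }
      prof[c1, nb$pos[i], slot] <- prof[c1, nb$pos[i], slot] + 1L
    }
  }
  .ifacevol_cache[[key]] <- prof
  prof
}

#' Synonymous/nonsynonymous site counts per codon
#'
#' Each codon position contributes one site, apportioned between synonymous
#' and nonsynonymous according to the fraction of possible single-nucleotide
#' changes of each kind (changes to stop codons excluded from the
#' denominator). With `kappa != 1`, changes are weighted by the
#' transition/transversion rate ratio, giving mutational-opportunity site
#' counts in the style of Yang & Nielsen's pairwise estimator.
#'
#' @param code Genetic code name.
#' @param kappa Transition/transversion rate ratio used to weight changes
#'   (1 = unweighted, the Nei-Gojobori convention).
#' @return A matrix with one row per sense codon and columns `S` and `N`
#'   (`S + N = 3` for every codon).
#' @export
codon_sites <- function(code = "vertebrate_mito", kappa = 1) {
  prof <- codon_site_profile(code)
  w_syn <- kappa * prof[, , "syn_ts"] + prof[, , "syn_tv"]
  w_all <- w_syn + kappa * prof[, , "non_ts"] + prof[, , "non_tv"]
  frac <- ifelse(w_all > 0, w_syn / w_all, 0)
  S <- rowSums(frac)
  cbind(S = S, N = 3 - S)
}

# Minimal mutational pathways between two codons (permutations of the
# differing positions). Returns a matrix with one row per pathway:
# n_ts (transition steps), nd, sd. Pathways through stop codons are
# excluded; if all are blocked, all pathways are returned as a fallback
# (rare; only multi-hit pairs flanking a stop).
codon_pair_paths <- function(c1, c2, gc) {
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  diffpos <- which(n1 != n2)
  d <- length(diffpos)
  if (d == 0L) return(matrix(0, 1, 3, dimnames = list(NULL, c("n_ts", "nd", "sd"))))
  perms <- if (d == 1L) list(diffpos) else {
    idx <- if (d == 2L) list(c(1, 2), c(2, 1)) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(o) diffpos[o])
  }
  walk <- function(ord) {
    cur <- n1
    nd <- 0; sd <- 0; nts <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- n2[pos]
      ca <- paste(cur, collapse = ""); cb <- paste(nxt, collapse = "")
      if (gc$aa[[cb]] == "*") ok <- FALSE
      if (is_transition(cur[pos], n2[pos])) nts <- nts + 1
      if (gc$aa[[ca]] == gc$aa[[cb]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nts, nd, sd, ok)
  }
  res <- t(vapply(perms, walk, numeric(4)))
  keep <- res[, 4] == 1
  if (!any(keep)) keep <- rep(TRUE, nrow(res))
  out <- res[keep, 1:3, drop = FALSE]
  colnames(out) <- c("n_ts", "nd", "sd")
  out
}

# kappa-independent pathway decomposition for all sense-codon pairs,
# cached per code: columns i, j (i < j), n_ts, nd, sd, one row per
# admissible minimal pathway.
codon_path_table <- function(code) {
  key <- paste0("paths_", code)
  if (!is.null(.ifacevol_cache[[key]])) return(.ifacevol_cache[[key]])
  gc <- genetic_code(code)
  n <- gc$n_state
  rows <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- codon_pair_paths(gc$sense[i], gc$sense[j], gc)
      k <- k + 1L
      rows[[k]] <- cbind(i = i, j = j, p)
    }
  }
  out <- do.call(rbind, rows)
  .ifacevol_cache[[key]] <- out
  out
}

#' Pathway-averaged substitution counts for all sense-codon pairs
#'
#' For every pair of sense codons, the numbers of nonsynonymous and
#' synonymous differences are averaged over all minimal mutational pathways
#' between the two codons. Pathways passing through a stop codon are
#' excluded; with `kappa != 1` pathways are weighted by kappa per
#' transition step. The kappa-independent pathway decomposition is cached,
#' so reweighting for a new kappa is cheap.
#'
#' @param code Genetic code name.
#' @param kappa Pathway weighting ratio (1 = equal weights).
#' @return List of two `n_state x n_state` matrices `ND` and `SD`
#'   (`ND + SD` equals the nucleotide difference count for each pair).
#' @export
codon_pair_counts <- function(code = "vertebrate_mito", kappa = 1) {
  key <- paste0("paircnt_", code, "_", format(kappa, digits = 10))
  if (!is.null(.ifacevol_cache[[key]])) return(.ifacevol_cache[[key]])
  gc <- genetic_code(code)
  n <- gc$n_state
  pt <- codon_path_table(code)
  w <- kappa^pt[, "n_ts"]
  f <- (pt[, "i"] - 1) * n + pt[, "j"]
  den <- rowsum(w, f)
  nd <- rowsum(w * pt[, "nd"], f) / den
  sd_ <- rowsum(w * pt[, "sd"], f) / den
  ND <- matrix(0, n, n, dimnames = list(gc$sense, gc$sense))
  SD <- ND
  ids <- as.integer(rownames(den))
  ii <- (ids - 1) %/% n + 1
  jj <- ids - (ii - 1) * n
  ND[cbind(ii, jj)] <- nd; ND[cbind(jj, ii)] <- nd
  SD[cbind(ii, jj)] <- sd_; SD[cbind(jj, ii)] <- sd_
  out <- list(ND = ND, SD = SD)
  .ifacevol_cache[[key]] <- out
  out
}
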