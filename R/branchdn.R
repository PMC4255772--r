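# Per-branch nonsynonymous divergence: conditional expected labelled
# substitution counts under a fitted codon model, apportioned branch by
# branch, and the per-branch difference statistic between two partitions.

# Proportion of the neutral mutational flux that is nonsynonymous, given
# kappa and pi: used to convert expected nonsynonymous substitution counts
# into substitutions per nonsynonymous site (sites = 3 * codons * rho_N).
nonsyn_site_fraction <- function(pi, kappa, code) {
  ch <- codon_change_structure(code)
  w <- pi[ch$from] * pi[ch$to] * ifelse(ch$ts, kappa, 1)
  sum(w[ch$nonsyn]) / sum(w)
}

# Expected nonsynonymous substitution count per branch for one alignment
# under a fixed (pi, kappa, omega): up/down pruning passes plus the
# endpoint-conditioned labelled-jump integral per branch.
expected_branch_counts <- function(tp, eg, pat, w) {
  n <- length(eg$pi)
  nedge <- nrow(tp$edge)
  Plist <- lapply(tp$len, function(t) prob_matrix(eg, t))
  Jlist <- lapply(tp$len, function(t) labelled_integral(eg, t, "nonsyn"))
  up <- prune_pass(tp, Plist, pat, n, keep_messages = TRUE)
  partial <- up$partial; msgs <- up$msgs
  npat <- ncol(pat)
  # children edges per internal node
  kids <- split(seq_len(nedge), tp$edge[, 1])
  down <- vector("list", tp$ntip + tp$nnode)
  down[[tp$root]] <- matrix(eg$pi, n, npat)
  counts <- numeric(nedge)
  # process edges parent-before-child (reverse postorder)
  for (e in rev(seq_len(nedge))) {
    parent <- tp$edge[e, 1]; child <- tp$edge[e, 2]
    sibs <- setdiff(kids[[as.character(parent)]], e)
    excl <- down[[parent]]
    for (f in sibs) excl <- excl * msgs[[f]]
    # per-pattern normaliser: total likelihood factorised across this branch
    Upv <- partial[[child]]
    denom <- colSums(excl * (Plist[[e]] %*% Upv))
    num <- colSums(excl * (Jlist[[e]] %*% Upv))
    ok <- denom > 0
    counts[e] <- sum(w[ok] * num[ok] / denom[ok])
    if (child > tp$ntip) {
      dc <- crossprod(Plist[[e]], excl)
      # rescale per pattern; only likelihood ratios of this quantity are used
      mx <- apply(dc, 2, max)
      mx[mx <= 0] <- 1
      down[[child]] <- dc / rep(mx, each = nrow(dc))
    }
  }
  counts
}

#' Per-branch nonsynonymous divergence for partitioned alignments
#'
#' For each branch of a fixed tree and each partition, computes the
#' expected number of nonsynonymous substitutions given the tip data
#' (conditional expected Markov jump counts under the fitted model, with
#' nonsynonymous transitions labelled), divided by the partition's
#' nonsynonymous site count (mutational-opportunity definition under the
#' fitted kappa and pi). When two partition names are supplied, the
#' per-branch difference `dN[first] - dN[second]` is returned as well; the
#' motivating analysis contrasts residues contacting the other genome's
#' subunits against residues contacting same-genome subunits.
#'
#' @param tree Tree with fixed branch lengths (e.g. from [fit_m0()]).
#' @param parts Named list of `codon_alignment` objects.
#' @param omegas Named vector of partition omegas (e.g. from
#'   [fit_fixed_sites()]).
#' @param kappa Shared transition/transversion ratio.
#' @param contrast Character vector of two partition names for the
#'   difference statistic, or `NULL` to skip.
#' @return A `branch_dn`: list with `dn` (matrix branches x partitions),
#'   `difference` (per-branch vector or `NULL`), `edge` (edge matrix of the
#'   postorder tree), `n_sites` (nonsynonymous sites per partition),
#'   `expected_counts`.
#' @export
branch_dn <- function(tree, parts, omegas, kappa, contrast = NULL) {
  keep <- !vapply(parts, is.null, logical(1))
  parts <- parts[keep]
  stopifnot(length(parts) >= 1)
  om <- omegas[names(parts)]
  if (any(is.na(om))) stop("missing omega for partition: ",
                           paste(names(parts)[is.na(om)], collapse = ", "))
  cs1 <- compress_for_tree(tree, parts[[1]])
  nedge <- nrow(cs1$tp$edge)
  dn <- matrix(NA_real_, nedge, length(parts),
               dimnames = list(NULL, names(parts)))
  cnt <- dn
  nsites <- setNames(numeric(length(parts)), names(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    pi <- f3x4_frequencies(p)
    cs <- compress_for_tree(tree, p)
    eg <- codon_eigen(pi, kappa, om[i], p$code)
    counts <- expected_branch_counts(cs$tp, eg, cs$pc$pat, cs$pc$w)
    nsites[i] <- 3 * p$n_col * nonsyn_site_fraction(eg$pi, kappa, p$code)
    cnt[, i] <- counts
    dn[, i] <- counts / nsites[i]
  }
  difference <- NULL
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2, all(contrast %in% names(parts)))
    difference <- dn[, contrast[1]] - dn[, contrast[2]]
  }
  structure(list(dn = dn, difference = difference, edge = cs1$tp$edge,
                 n_sites = nsites, expected_counts = cnt,
                 contrast = contrast),
            class = "branch_dn")
}

#' @export
print.branch_dn <- function(x, ...) {
  cat("branch_dn:", nrow(x$dn), "branches x", ncol(x$dn), "partitions\n")
  if (!is.null(x$difference))
    cat(sprintf("  difference %s - %s: mean = %.5f, positive on %.1f%% of branches\n",
                x$contrast[1], x$contrast[2], mean(x$difference),
                100 * mean(x$difference > 0)))
  invisible(x)
}

#' Write a per-branch dN table as TSV
#' @param bdn A `branch_dn`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_branch_dn_tsv <- function(bdn, path) {
  df <- data.frame(parent = bdn$edge[, 1], child = bdn$edge[, 2], bdn$dn)
  if (!is.null(bdn$difference)) df$difference <- bdn$difference
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
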