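# Empirical null distribution of Sigma-dN by random codon-subset draws.

#' Empirical null distribution of Sigma-dN under random codon subsets
#'
#' Repeatedly draws `m` distinct codon columns uniformly at random from the
#' alignment, computes Sigma-dN on each induced sub-alignment, and returns
#' the resulting empirical distribution. This is the reference distribution
#' against which the Sigma-dN of a structurally defined subset of the same
#' size is contrasted: a class whose observed Sigma-dN falls in the lower
#' tail is exceptionally conserved, in the upper tail exceptionally
#' variable.
#'
#' Per-pair, per-column substitution statistics are computed once for the
#' full alignment, so each replicate costs only row sums over the drawn
#' columns; the default replicate count of 10^4 is therefore practical even
#' for many taxa.
#'
#' @param aln A `codon_alignment`.
#' @param m Subset size (number of columns drawn per replicate).
#' @param B Number of replicates (default 10000).
#' @param seed RNG seed (draws are reproducible given the seed).
#' @param method Pairwise divergence method (see [pairwise_dn()]).
#' @return A `null_distribution`: list with `values` (length `B`), `B`, `m`,
#'   `seed`, `method`, `kappa`.
#' @export
sample_null_sumdn <- function(aln, m, B = 10000L, seed = 1L,
                              method = c("yn00", "ng86")) {
  method <- match.arg(method)
  if (m < 1 || m > aln$n_col)
    stop("subset size m = ", m, " outside [1, ", aln$n_col, "]")
  if (B < 1) stop("B must be >= 1")
  ps <- pair_column_stats(aln, method = method)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  values <- vapply(seq_len(B), function(b) {
    cols <- sample.int(ps$n_col, m, replace = FALSE)
    sumdn_from_stats(ps, cols)$sum_dn
  }, numeric(1))
  structure(list(values = values, B = B, m = m, seed = seed,
                 method = method, kappa = ps$kappa),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: B = %d draws of m = %d columns; mean = %.4f, sd = %.4f\n",
              x$B, x$m, mean(x$values), sd(x$values)))
  invisible(x)
}

#' Empirical tail probability of an observed Sigma-dN against a null
#'
#' Add-one tail fraction: lower tail `(1 + #{draws <= observed}) / (B + 1)`,
#' upper tail analogously with `>=`. The add-one smoothing keeps p in
#' (0, 1] so that no finite resampling run reports an exact zero.
#'
#' @param observed Observed Sigma-dN.
#' @param null A `null_distribution` (or numeric vector of draws).
#' @param tail `"lower"` (conserved) or `"upper"` (variable).
#' @return Scalar empirical p value.
#' @export
empirical_pvalue <- function(observed, null, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  v <- if (inherits(null, "null_distribution")) null$values else as.numeric(null)
  if (length(v) == 0L) stop("empty null distribution")
  r <- if (tail == "lower") sum(v <= observed) else sum(v >= observed)
  (1 + r) / (length(v) + 1)
}
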