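# Pairwise nonsynonymous divergence, Sigma-dN accumulation, interaction ratio.

# Jukes-Cantor multiple-hit correction of a proportion of differences;
# saturated proportions (p >= 3/4) are undefined.
jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

# Integer-encode a codon alignment against the sense-codon state space.
# Returns taxa x columns integer matrix (NA for gapped/masked codons).
encode_states <- function(aln, gc = genetic_code(aln$code)) {
  idx <- match(aln$codons, gc$sense)
  matrix(idx, nrow = nrow(aln$codons), ncol = ncol(aln$codons),
         dimnames = dimnames(aln$codons))
}

#' Estimate the transition/transversion rate ratio from third codon positions
#'
#' Kimura two-parameter estimate pooled over third positions of all usable
#' codon pairs across the alignment. Third positions are predominantly
#' synonymous, making this a pragmatic alignment-level kappa for weighting
#' site and pathway counts. Falls back to `fallback` when the estimator is
#' undefined (saturation or no variation).
#'
#' @param aln A `codon_alignment`.
#' @param fallback Value returned when the estimate is undefined.
#' @return Scalar kappa (> 0).
#' @export
estimate_kappa <- function(aln, fallback = 2) {
  third <- substr(aln$codons, 3, 3)
  dim(third) <- dim(aln$codons)
  taxa <- nrow(third)
  if (taxa < 2) return(fallback)
  ts_n <- 0; tv_n <- 0; tot <- 0
  purine <- c("A", "G")
  for (i in seq_len(taxa - 1)) {
    for (j in (i + 1):taxa) {
      a <- third[i, ]; b <- third[j, ]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      a <- a[ok]; b <- b[ok]
      diff <- a != b
      same_type <- (a %in% purine) == (b %in% purine)
      ts_n <- ts_n + sum(diff & same_type)
      tv_n <- tv_n + sum(diff & !same_type)
      tot <- tot + length(a)
    }
  }
  if (tot == 0) return(fallback)
  P <- ts_n / tot; Q <- tv_n / tot
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(fallback)
  s <- -0.5 * log(1 - 2 * P - Q) + 0.25 * log(1 - 2 * Q)  # alpha t
  v <- -0.5 * log(1 - 2 * Q)                               # 2 beta t
  if (v <= 0 || s <= 0) return(fallback)
  kappa <- 2 * s / v
  max(kappa, 0.1)
}

# Per-pair, per-column substitution statistics for the whole alignment.
# Central cache used by sum_dn and the resampling null: for each unordered
# taxon pair p and column c it stores pathway-averaged nonsynonymous and
# synonymous difference counts and the pair-averaged site counts, so that
# Sigma-dN over any column subset reduces to row sums.
pair_column_stats <- function(aln, method = c("yn00", "ng86"), kappa = NULL) {
  method <- match.arg(method)
  gc <- genetic_code(aln$code)
  if (method == "yn00") {
    if (is.null(kappa)) kappa <- estimate_kappa(aln)
  } else kappa <- 1
  st <- encode_states(aln, gc)
  cnt <- codon_pair_counts(aln$code, kappa = kappa)
  sites <- codon_sites(aln$code, kappa = kappa)
  taxa <- nrow(st)
  if (taxa < 2) stop("need at least 2 taxa")
  pairs <- t(combn(taxa, 2))
  np <- nrow(pairs); nc <- ncol(st)
  ND <- matrix(0, np, nc); SD <- matrix(0, np, nc)
  NS <- matrix(0, np, nc); SS <- matrix(0, np, nc)
  for (p in seq_len(np)) {
    a <- st[pairs[p, 1], ]; b <- st[pairs[p, 2], ]
    ok <- !is.na(a) & !is.na(b)
    ia <- a[ok]; ib <- b[ok]
    idx <- cbind(ia, ib)
    ND[p, ok] <- cnt$ND[idx]
    SD[p, ok] <- cnt$SD[idx]
    NS[p, ok] <- (sites[ia, "N"] + sites[ib, "N"]) / 2
    SS[p, ok] <- (sites[ia, "S"] + sites[ib, "S"]) / 2
  }
  list(pairs = pairs, ND = ND, SD = SD, NS = NS, SS = SS,
       kappa = kappa, method = method, taxa = aln$taxa, n_col = nc)
}

# Sigma-dN over a column subset, from precomputed pair-column stats.
sumdn_from_stats <- function(ps, cols = NULL) {
  if (is.null(cols)) cols <- seq_len(ps$n_col)
  nd <- rowSums(ps$ND[, cols, drop = FALSE])
  ns <- rowSums(ps$NS[, cols, drop = FALSE])
  pN <- ifelse(ns > 0, nd / ns, NA_real_)
  dN <- jc_correct(pN)
  list(sum_dn = sum(dN, na.rm = TRUE),
       dN = dN,
       n_undefined = sum(is.na(dN)))
}

#' Pairwise nonsynonymous and synonymous divergence between two sequences
#'
#' Counting estimator of dN and dS for one sequence pair. Site counts are
#' apportioned per codon position from the possible single-nucleotide
#' changes (stop changes excluded) and averaged over the two sequences;
#' differences at multi-hit codons are averaged over all minimal mutational
#' pathways avoiding stop codons; proportions are corrected for multiple
#' hits with the Jukes-Cantor formula. `method = "ng86"` is the classical
#' unweighted Nei-Gojobori estimator; `method = "yn00"` (default) weights
#' sites and pathways by a transition/transversion ratio kappa in the
#' spirit of Yang & Nielsen's pairwise method.
#'
#' @param s1,s2 Character vectors of codons (equal length; `NA` = gap).
#' @param code Genetic code name.
#' @param method `"yn00"` or `"ng86"`.
#' @param kappa Transition/transversion ratio for `"yn00"`; `NULL` to use 2.
#' @return A list of class `pairwise_dn`: `dN`, `dS` (NA when saturated),
#'   `pN`, `pS`, `Nd`, `Sd`, `N_sites`, `S_sites`, `kappa_hat`,
#'   `usable_codons`.
#' @export
pairwise_dn <- function(s1, s2, code = "vertebrate_mito",
                        method = c("yn00", "ng86"), kappa = NULL) {
  method <- match.arg(method)
  stopifnot(length(s1) == length(s2))
  k <- if (method == "ng86") 1 else if (is.null(kappa)) 2 else kappa
  gc <- genetic_code(code)
  i1 <- match(s1, gc$sense); i2 <- match(s2, gc$sense)
  ok <- !is.na(i1) & !is.na(i2)
  usable <- sum(ok)
  if (usable == 0L)
    return(structure(list(dN = NA_real_, dS = NA_real_, pN = NA_real_,
                          pS = NA_real_, Nd = 0, Sd = 0, N_sites = 0,
                          S_sites = 0, kappa_hat = k, usable_codons = 0L),
                     class = "pairwise_dn"))
  cnt <- codon_pair_counts(code, kappa = k)
  sites <- codon_sites(code, kappa = k)
  idx <- cbind(i1[ok], i2[ok])
  Nd <- sum(cnt$ND[idx]); Sd <- sum(cnt$SD[idx])
  N <- sum((sites[i1[ok], "N"] + sites[i2[ok], "N"]) / 2)
  S <- sum((sites[i1[ok], "S"] + sites[i2[ok], "S"]) / 2)
  pN <- if (N > 0) Nd / N else NA_real_
  pS <- if (S > 0) Sd / S else NA_real_
  structure(list(dN = jc_correct(pN), dS = jc_correct(pS), pN = pN, pS = pS,
                 Nd = Nd, Sd = Sd, N_sites = N, S_sites = S, kappa_hat = k,
                 usable_codons = usable),
            class = "pairwise_dn")
}

#' @export
print.pairwise_dn <- function(x, ...) {
  cat(sprintf("pairwise_dn: dN = %.5f dS = %.5f (Nd = %.2f, Sd = %.2f, N = %.1f, S = %.1f, %d codons)\n",
              x$dN, x$dS, x$Nd, x$Sd, x$N_sites, x$S_sites, x$usable_codons))
  invisible(x)
}

#' Sum of pairwise nonsynonymous divergences over all sequence pairs
#'
#' Computes dN for every unordered taxon pair of the alignment and returns
#' their sum (Sigma-dN), the package's evolvability summary for a codon
#' subset. Pairs with undefined dN (no usable codons or Jukes-Cantor
#' saturation) are excluded and counted. A codon-column bootstrap provides
#' a standard error.
#'
#' @param aln A `codon_alignment` (>= 2 taxa).
#' @param method `"yn00"` or `"ng86"` (see [pairwise_dn()]).
#' @param boot_reps Bootstrap replicates for the standard error (0 = none).
#' @param seed Seed for the bootstrap.
#' @return A `divergence_summary`: list with `sum_dn`, `n_pairs`,
#'   `n_undefined_pairs`, `se_sum_dn`, `kappa`, `method`, `dN` (per-pair
#'   vector), `pairs` (index matrix).
#' @export
sum_dn <- function(aln, method = c("yn00", "ng86"), boot_reps = 200,
                   seed = 1L) {
  method <- match.arg(method)
  if (length(aln$taxa) < 2) stop("need at least 2 taxa")
  ps <- pair_column_stats(aln, method = method)
  full <- sumdn_from_stats(ps)
  se <- NA_real_
  if (boot_reps > 0 && ps$n_col > 1) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    reps <- vapply(seq_len(boot_reps), function(b) {
      cols <- sample.int(ps$n_col, ps$n_col, replace = TRUE)
      sumdn_from_stats(ps, cols)$sum_dn
    }, numeric(1))
    se <- sd(reps)
  }
  structure(list(sum_dn = full$sum_dn,
                 n_pairs = nrow(ps$pairs) - full$n_undefined,
                 n_undefined_pairs = full$n_undefined,
                 se_sum_dn = se, kappa = ps$kappa, method = method,
                 dN = full$dN, pairs = ps$pairs),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("divergence_summary: sum dN = %.4f over %d pairs (%d undefined), SE = %.4f\n",
              x$sum_dn, x$n_pairs, x$n_undefined_pairs, x$se_sum_dn))
  invisible(x)
}

#' Interaction ratio between two Sigma-dN summaries
#'
#' The ratio Sigma-dN(a) / Sigma-dN(b). Values above 1 indicate faster
#' nonsynonymous evolution in the numerator residue class; below 1, slower.
#'
#' @param a,b `divergence_summary` objects (or numeric Sigma-dN values).
#' @return A list with `ratio` (NA with `defined = FALSE` when the
#'   denominator is zero), `sum_dn_num`, `sum_dn_den`, `defined`.
#' @export
interaction_ratio <- function(a, b) {
  va <- if (inherits(a, "divergence_summary")) a$sum_dn else as.numeric(a)
  vb <- if (inherits(b, "divergence_summary")) b$sum_dn else as.numeric(b)
  if (!is.finite(vb) || vb == 0)
    return(list(ratio = NA_real_, sum_dn_num = va, sum_dn_den = vb,
                defined = FALSE))
  list(ratio = va / vb, sum_dn_num = va, sum_dn_den = vb, defined = TRUE)
}

# Save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
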