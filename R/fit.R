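# Maximum-likelihood fits: M0, fixed-sites partition omegas, M1a/M2a LRT.

.omega_bounds <- c(1e-4, 99)
.kappa_bounds <- c(0.01, 100)
.bl_bounds <- c(1e-8, 20)

# Shared objective scaffolding: pattern-compress once, then evaluate the
# pruning likelihood for parameter proposals.
compress_for_tree <- function(tree, aln) {
  gc <- genetic_code(aln$code)
  if (any(aln$codons %in% gc$stops))
    stop("alignment contains stop codons; mask them before fitting")
  tp <- prepare_tree(tree, aln$taxa)
  states <- encode_states(aln, gc)[tp$tip_index, , drop = FALSE]
  pc <- pattern_compress(states)
  list(tp = tp, pc = pc, gc = gc)
}

#' Fit the one-ratio (M0) codon model
#'
#' Maximises the pruning log-likelihood over all branch lengths, kappa and a
#' single omega, with F3x4 frequencies fixed at their empirical values. The
#' fitted branch lengths (expected nucleotide substitutions per codon) are
#' intended to be cached and reused by the fixed-sites and site-model fits.
#'
#' @param tree An `ape::phylo` giving the (fixed) topology; existing branch
#'   lengths are used as starting values when present.
#' @param aln A `codon_alignment`.
#' @param pi Codon frequencies (default F3x4 from `aln`).
#' @param init Named list of starting values (`kappa`, `omega`).
#' @param control Passed to [stats::nlminb()].
#' @return A `fit_result`: list with `lnL`, `kappa`, `omega`, `tree` (branch
#'   lengths replaced by estimates), `pi`, `convergence` (0 = ok),
#'   `n_evals`.
#' @export
fit_m0 <- function(tree, aln, pi = NULL,
                   init = list(kappa = 2, omega = 0.2),
                   control = list(rel.tol = 1e-9)) {
  if (length(aln$taxa) < 3) stop("need >= 3 taxa")
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  cs <- compress_for_tree(tree, aln)
  nb <- nrow(cs$tp$edge)
  bl0 <- cs$tp$len
  bl0[bl0 <= .bl_bounds[1]] <- 0.05
  par0 <- c(log(bl0), log(init$kappa), log(init$omega))
  lower <- c(rep(log(.bl_bounds[1]), nb), log(.kappa_bounds[1]),
             log(.omega_bounds[1]))
  upper <- c(rep(log(.bl_bounds[2]), nb), log(.kappa_bounds[2]),
             log(.omega_bounds[2]))
  nev <- 0L
  obj <- function(par) {
    nev <<- nev + 1L
    tp <- cs$tp
    tp$len <- exp(par[seq_len(nb)])
    eg <- codon_eigen(pi, exp(par[nb + 1]), exp(par[nb + 2]), aln$code)
    -block_loglik(tp, eg, cs$pc$pat, cs$pc$w)
  }
  opt <- nlminb(par0, obj, lower = lower, upper = upper, control = control)
  tr <- cs$tp$tree
  tr$edge.length <- exp(opt$par[seq_len(nb)])
  structure(list(lnL = -opt$objective, kappa = exp(opt$par[nb + 1]),
                 omega = exp(opt$par[nb + 2]), tree = tr, pi = pi,
                 convergence = opt$convergence, n_evals = nev,
                 message = opt$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: lnL = %.4f, kappa = %.3f\n", x$lnL, x$kappa))
  if (!is.null(x$omega) && length(x$omega) == 1)
    cat(sprintf("  omega = %.4f\n", x$omega))
  if (!is.null(x$omegas)) {
    cat("  partition omegas:\n")
    print(round(x$omegas, 4))
  }
  invisible(x)
}

#' Fit a fixed-sites partition model (one omega per site class)
#'
#' Branch lengths are held fixed (typically at M0 estimates); one omega is
#' estimated per partition with kappa shared across partitions. Codon
#' frequencies are F3x4, computed per partition by default so each class
#' carries its own base composition. Empty partitions are skipped with a
#' warning. Per-partition standard errors come from the curvature of the
#' profile log-likelihood in log-omega.
#'
#' @param tree Tree with fixed branch lengths (substitutions per codon).
#' @param parts Named list of `codon_alignment` objects (same taxa), one per
#'   partition; `NULL` entries allowed for empty classes.
#' @param shared_pi If `TRUE`, one F3x4 vector from the concatenation is
#'   shared across partitions.
#' @param init Starting values (`kappa`, `omega`).
#' @param control Passed to [stats::nlminb()].
#' @return A `fit_result` with `omegas` (named vector ordered as `parts`),
#'   `se_omegas`, shared `kappa`, `lnL`.
#' @export
fit_fixed_sites <- function(tree, parts, shared_pi = FALSE,
                            init = list(kappa = 2, omega = 0.2),
                            control = list(rel.tol = 1e-9)) {
  keep <- !vapply(parts, is.null, logical(1))
  keep <- keep & vapply(parts, function(p)
    !is.null(p) && p$n_col > 0, logical(1))
  if (!any(keep)) stop("all partitions are empty")
  if (any(!keep))
    warning("skipping empty partitions: ",
            paste(names(parts)[!keep], collapse = ", "))
  used <- parts[keep]
  np <- length(used)
  pis <- if (shared_pi) {
    allc <- do.call(cbind, lapply(used, function(p) p$codons))
    pi1 <- f3x4_frequencies(codon_alignment(allc, code = used[[1]]$code))
    rep(list(pi1), np)
  } else lapply(used, f3x4_frequencies)
  css <- lapply(used, function(p) compress_for_tree(tree, p))
  nev <- 0L
  part_lnl <- function(k, om, i) {
    eg <- codon_eigen(pis[[i]], k, om, used[[i]]$code)
    block_loglik(css[[i]]$tp, eg, css[[i]]$pc$pat, css[[i]]$pc$w)
  }
  obj <- function(par) {
    nev <<- nev + 1L
    k <- exp(par[1])
    -sum(vapply(seq_len(np), function(i)
      part_lnl(k, exp(par[1 + i]), i), numeric(1)))
  }
  par0 <- c(log(init$kappa), rep(log(init$omega), np))
  lower <- c(log(.kappa_bounds[1]), rep(log(.omega_bounds[1]), np))
  upper <- c(log(.kappa_bounds[2]), rep(log(.omega_bounds[2]), np))
  opt <- nlminb(par0, obj, lower = lower, upper = upper, control = control)
  k_hat <- exp(opt$par[1])
  om_hat <- exp(opt$par[-1])
  # profile curvature SE on the log scale, delta method back to omega
  se <- vapply(seq_len(np), function(i) {
    h <- 1e-4
    l0 <- part_lnl(k_hat, om_hat[i], i)
    lp <- part_lnl(k_hat, om_hat[i] * exp(h), i)
    lm <- part_lnl(k_hat, om_hat[i] * exp(-h), i)
    d2 <- (lp - 2 * l0 + lm) / h^2
    if (is.finite(d2) && d2 < 0) om_hat[i] / sqrt(-d2) else NA_real_
  }, numeric(1))
  omegas <- setNames(rep(NA_real_, length(parts)), names(parts))
  ses <- omegas
  omegas[names(used)] <- om_hat
  ses[names(used)] <- se
  structure(list(lnL = -opt$objective, kappa = k_hat, omegas = omegas,
                 se_omegas = ses, convergence = opt$convergence,
                 n_evals = nev, tree = tree),
            class = "fit_result")
}

# Mixture likelihood machinery: site likelihoods per omega class, mixing
# proportions profiled out by EM (fast inner loop, no pruning). All omega
# classes share one rate scale so that branch lengths stay expected
# substitutions per codon under the fitted mixture: the common scale
# c = sum_k p_k mu_k depends on the proportions, so the site-likelihood
# matrices are recomputed until c stabilises.
mixture_lnl <- function(cs, pis_pi, code, kappa, omegas, em_iter = 2000,
                        em_tol = 1e-10, scale_iter = 10, scale_tol = 1e-5,
                        p_init = NULL, fixed_scale = NULL) {
  K <- length(omegas)
  npat <- length(cs$pc$w)
  w <- cs$pc$w
  mus <- vapply(omegas, function(om)
    gy94_mean_rate(pis_pi, kappa, om, code), numeric(1))
  p <- if (is.null(p_init) || length(p_init) != K) rep(1 / K, K) else p_init
  cscale <- if (is.null(fixed_scale)) sum(p * mus) else fixed_scale
  if (!is.null(fixed_scale)) scale_iter <- 1L
  lnl <- -Inf
  for (outer in seq_len(scale_iter)) {
    L <- matrix(0, npat, K)
    S <- matrix(0, npat, K)
    for (k in seq_len(K)) {
      eg <- codon_eigen(pis_pi, kappa, omegas[k], code,
                        scale_factor = cscale)
      sl <- block_site_lik(cs$tp, eg, cs$pc$pat)
      L[, k] <- sl$lik
      S[, k] <- sl$scale_log
    }
    smax <- apply(S, 1, max)
    Ladj <- L * exp(S - smax)
    lnl_old <- -Inf
    for (it in seq_len(em_iter)) {
      mix <- as.numeric(Ladj %*% p)
      if (any(mix <= 0)) return(list(lnL = -Inf, p = p, scale = cscale))
      lnl <- sum(w * (log(mix) + smax))
      resp <- (Ladj * rep(p, each = npat)) / mix
      p <- colSums(w * resp) / sum(w)
      if (abs(lnl - lnl_old) < em_tol) break
      lnl_old <- lnl
    }
    cnew <- sum(p * mus)
    if (abs(cnew - cscale) < scale_tol * cscale) { cscale <- cnew; break }
    cscale <- cnew
  }
  mix <- as.numeric(Ladj %*% p)
  list(lnL = sum(w * (log(mix) + smax)), p = p, scale = cscale)
}

#' Likelihood-ratio test of positive selection (M1a vs M2a)
#'
#' Fits the nearly-neutral site model M1a (site classes with omega0 < 1 and
#' omega1 = 1) and the positive-selection model M2a (an extra class with
#' omega2 > 1) on a fixed tree, and compares them with a chi-squared test
#' on 2 degrees of freedom. Mixing proportions are profiled out by EM
#' inside each likelihood evaluation; M2a uses multiple starting points for
#' the extra omega class.
#'
#' @param tree Tree with fixed branch lengths.
#' @param aln A `codon_alignment`.
#' @param pi Codon frequencies (default F3x4 from `aln`).
#' @param n_starts Number of starting points for M2a.
#' @param control Passed to [stats::nlminb()].
#' @return List with `lnL_m1a`, `lnL_m2a`, `stat` (2 delta lnL, floored at
#'   0), `p` (chi-squared, 2 df), `m1a` and `m2a` parameter lists, and
#'   `optimizer_failure` (TRUE when M2a falls materially below M1a).
#' @export
fit_site_models_lrt <- function(tree, aln, pi = NULL, n_starts = 3,
                                control = list(rel.tol = 1e-8)) {
  if (is.null(pi)) pi <- f3x4_frequencies(aln)
  cs <- compress_for_tree(tree, aln)
  code <- aln$code
  # Optimisation runs at a frozen common scale (cheap, deterministic
  # objective: one pruning pass per omega class and EM over proportions);
  # the self-consistent scale c = sum p_k mu_k is then re-solved at the
  # optimum and the optimisation repeated once if it moved.
  omegas_of <- list(
    m1a = function(par) c(exp(par[2]), 1),
    m2a = function(par) c(exp(par[2]), 1, 1 + exp(par[3])))
  fit_model <- function(model, starts, lower, upper) {
    om_fun <- omegas_of[[model]]
    best <- NULL
    for (s in starts) {
      csc <- mixture_lnl(cs, pi, code, exp(s[1]), om_fun(s))$scale
      for (cycle in 1:2) {
        obj <- function(par)
          -mixture_lnl(cs, pi, code, exp(par[1]), om_fun(par),
                       fixed_scale = csc)$lnL
        o <- try(nlminb(s, obj, lower = lower, upper = upper,
                        control = control), silent = TRUE)
        if (inherits(o, "try-error")) break
        full <- mixture_lnl(cs, pi, code, exp(o$par[1]), om_fun(o$par))
        if (abs(full$scale - csc) < 1e-3 * csc) break
        csc <- full$scale
        s <- o$par
      }
      if (inherits(o, "try-error")) next
      cand <- list(par = o$par, lnL = full$lnL, p = full$p)
      if (is.null(best) || cand$lnL > best$lnL) best <- cand
    }
    best
  }
  o1 <- fit_model("m1a",
                  starts = list(c(log(2), log(0.2)), c(log(4), log(0.7))),
                  lower = c(log(.kappa_bounds[1]), log(.omega_bounds[1])),
                  upper = c(log(.kappa_bounds[2]), log(0.999)))
  starts2 <- list(c(o1$par[1], o1$par[2], log(0.5)),
                  c(o1$par[1], o1$par[2], log(4)),
                  c(log(2), log(0.1), log(7)))[seq_len(max(1, n_starts))]
  o2 <- fit_model("m2a", starts = starts2,
                  lower = c(log(.kappa_bounds[1]), log(.omega_bounds[1]),
                            log(1e-3)),
                  upper = c(log(.kappa_bounds[2]), log(0.999), log(98)))
  fit1 <- list(lnL = o1$lnL, p = o1$p)
  fit2 <- list(lnL = o2$lnL, p = o2$p)
  best <- o2
  lnl1 <- fit1$lnL; lnl2 <- fit2$lnL
  failed <- lnl2 < lnl1 - 0.5
  # M1a is nested in M2a (p2 -> 0), so a materially better M1a means the
  # M2a search failed; report the nested bound in that case
  if (lnl2 < lnl1) lnl2 <- lnl1
  stat <- max(0, 2 * (lnl2 - lnl1))
  list(lnL_m1a = lnl1, lnL_m2a = lnl2, stat = stat,
       p = pchisq(stat, df = 2, lower.tail = FALSE),
       m1a = list(kappa = exp(o1$par[1]), omega0 = exp(o1$par[2]),
                  p = fit1$p),
       m2a = list(kappa = exp(best$par[1]), omega0 = exp(best$par[2]),
                  omega2 = 1 + exp(best$par[3]), p = fit2$p),
       optimizer_failure = failed)
}
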