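# Codon model: F3x4, rate matrix, pruning likelihood, ML fits.

test_that("F3x4 frequencies match hand-computed product normalisation", {
  # degenerate: single repeated codon
  aln <- codon_alignment(rbind(t1 = rep("AAA", 3), t2 = rep("AAA", 3)))
  pi <- f3x4_frequencies(aln)
  expect_equal(unname(pi[["AAA"]]), 1)
  expect_equal(sum(pi), 1)

  # small fixture: hand-counted positional frequencies
  m <- rbind(t1 = c("ATG", "TTT"), t2 = c("ATG", "TTC"))
  pi2 <- f3x4_frequencies(codon_alignment(m, code = "universal"))
  f1 <- c(A = 0.5, T = 0.5)               # position 1
  f2 <- c(T = 1)                          # position 2
  f3 <- c(G = 0.5, T = 0.25, C = 0.25)    # position 3
  raw <- function(cd) {
    p1 <- f1[substr(cd, 1, 1)]; p2 <- f2[substr(cd, 2, 2)]
    p3 <- f3[substr(cd, 3, 3)]
    prod(c(p1, p2, p3), na.rm = FALSE)
  }
  gcu <- genetic_code("universal")
  expected <- vapply(gcu$sense, raw, numeric(1))
  expected[is.na(expected)] <- 0
  expected <- expected / sum(expected)
  expect_equal(unname(pi2), unname(expected), tolerance = 1e-12)

  # uniform usage: uniform over sense codons
  gcv <- genetic_code("universal")
  uni <- codon_alignment(matrix(gcv$codons, nrow = 1,
                                dimnames = list("t1", NULL)),
                         code = "universal")
  # all 64 codons once: each nucleotide 16/64 at each position
  piu <- f3x4_frequencies(uni)
  expect_equal(unname(piu), rep(1 / 61, 61), tolerance = 1e-12)
})

test_that("GY94 generator satisfies its structural contracts", {
  gcv <- genetic_code("vertebrate_mito")
  set.seed(2)
  pi <- runif(60); pi <- pi / sum(pi); names(pi) <- gcv$sense
  Q <- gy94_rate_matrix(pi, kappa = 3, omega = 0.4)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance: diag(pi) Q is symmetric
  A <- pi * Q
  expect_lt(max(abs(A - t(A))), 1e-14)
  # omega = 0 removes all nonsynonymous rates
  Q0 <- gy94_rate_matrix(pi, kappa = 3, omega = 0, code = "vertebrate_mito")
  ch <- ifacevol:::codon_change_structure("vertebrate_mito")
  expect_true(all(Q0[cbind(ch$from, ch$to)][ch$nonsyn] == 0))
  # multi-nucleotide changes are zero
  multi <- outer(gcv$sense, gcv$sense, Vectorize(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) > 1))
  expect_true(all(Q[multi] == 0))
  expect_error(gy94_rate_matrix(pi, kappa = -1, omega = 0.5), "kappa")
  expect_error(gy94_rate_matrix(pi, kappa = 2, omega = -0.5), "omega")
})

test_that("transition probabilities conserve probability and match expm", {
  skip_if_not_installed("Matrix")
  gcv <- genetic_code("vertebrate_mito")
  set.seed(3)
  pi <- runif(60) + 0.2; pi <- pi / sum(pi); names(pi) <- gcv$sense
  eg <- ifacevol:::codon_eigen(pi, 2.5, 0.3)
  for (t in c(0.01, 0.1, 1, 10)) {
    P <- ifacevol:::prob_matrix(eg, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0))
  }
  P1 <- ifacevol:::prob_matrix(eg, 0.37)
  P2 <- as.matrix(Matrix::expm(eg$Q * 0.37))
  expect_lt(max(abs(P1 - P2)), 1e-9)
})

test_that("pruning equals exhaustive ancestral-state enumeration", {
  gcv <- genetic_code("vertebrate_mito")
  pi <- setNames(rep(1 / 60, 60), gcv$sense)
  for (n_tip in 3:4) {
    tr <- simulate_tree(n_tip, 0.2, seed = n_tip)
    sim <- simulate_codon_alignment(tr, c(a = 0.4), c(a = 3L), kappa = 3,
                                    seed = n_tip + 10)
    aln <- sim$alignment
    lnl <- tree_loglik(tr, aln, pi = pi, kappa = 3, omega = 0.4)
    # oracle: sum over all internal-node state combinations
    eg <- ifacevol:::codon_eigen(pi, 3, 0.4)
    P <- lapply(tr$edge.length, function(t) ifacevol:::prob_matrix(eg, t))
    states <- match(aln$codons, gcv$sense)
    dim(states) <- dim(aln$codons)
    states <- states[match(tr$tip.label, aln$taxa), , drop = FALSE]
    ntip <- length(tr$tip.label)
    n_int <- tr$Nnode
    brute <- 0
    for (col in seq_len(aln$n_col)) {
      tot <- 0
      grid <- do.call(expand.grid, rep(list(1:60), n_int))
      for (g in seq_len(nrow(grid))) {
        anc <- as.integer(grid[g, ])
        state_of <- function(node)
          if (node <= ntip) states[node, col] else anc[node - ntip]
        pr <- unname(pi[anc[1]])
        for (e in seq_len(nrow(tr$edge)))
          pr <- pr * P[[e]][state_of(tr$edge[e, 1]), state_of(tr$edge[e, 2])]
        tot <- tot + pr
      }
      brute <- brute + log(tot)
    }
    expect_equal(lnl, brute, tolerance = 1e-8)
  }
})

test_that("log-likelihood is invariant to the rooting of the unrooted tree", {
  tr <- simulate_tree(5, 0.2, seed = 7)
  sim <- simulate_codon_alignment(tr, c(a = 0.3), c(a = 20L), seed = 8)
  aln <- sim$alignment
  gcv <- genetic_code(aln$code)
  pi <- setNames(rep(1 / 60, 60), gcv$sense)
  base <- tree_loglik(tr, aln, pi = pi, kappa = 2, omega = 0.3)
  for (node in c(1L, 3L)) {
    tr2 <- ape::unroot(ape::root(tr, outgroup = tr$tip.label[node],
                                 resolve.root = FALSE))
    lnl2 <- tree_loglik(tr2, aln, pi = pi, kappa = 2, omega = 0.3)
    expect_equal(lnl2, base, tolerance = 1e-8)
  }
})

test_that("zero-branch limit reduces to the stationary log frequency", {
  gcv <- genetic_code("vertebrate_mito")
  pi <- setNames(rep(1 / 60, 60), gcv$sense)
  tr <- fixture_tree(3, bl = 1e-8)
  aln <- codon_alignment(rbind(t1 = "ATT", t2 = "ATT", t3 = "ATT"))
  lnl <- tree_loglik(tr, aln, pi = pi, kappa = 2, omega = 0.3)
  expect_equal(lnl, log(1 / 60), tolerance = 1e-4)
})

test_that("stop codons in the data are rejected with the site named", {
  tr <- fixture_tree(3, 0.1)
  aln <- codon_alignment(rbind(t1 = c("ATT", "TAA"), t2 = c("ATT", "ATT"),
                               t3 = c("ATT", "ATT")))
  aln$codons["t1", 2] <- "TAA"  # force a stop past the constructor
  expect_error(tree_loglik(tr, aln), "stop codon")
})

test_that("M0 recovers simulation parameters and is start-point stable", {
  tr <- simulate_tree(5, 0.12, seed = 31)
  sim <- simulate_codon_alignment(tr, c(a = 0.2), c(a = 400L), kappa = 4,
                                  seed = 32)
  fit <- fit_m0(tr, sim$alignment)
  expect_equal(fit$convergence, 0)
  expect_gt(fit$omega, 0.13)
  expect_lt(fit$omega, 0.3)
  expect_gt(fit$kappa, 2.5)
  expect_lt(fit$kappa, 6.5)
  # total fitted tree length near the truth
  expect_equal(sum(fit$tree$edge.length), sum(tr$edge.length),
               tolerance = 0.25)
  # refit from a perturbed start reaches the same optimum
  fit2 <- fit_m0(tr, sim$alignment, init = list(kappa = 9, omega = 0.9))
  expect_equal(fit2$lnL, fit$lnL, tolerance = 1e-4)
  expect_equal(fit2$omega, fit$omega, tolerance = 1e-2)
})

test_that("M0 on identical sequences drives branch lengths to the bound", {
  gcv <- genetic_code("vertebrate_mito")
  set.seed(63)
  s <- sample(gcv$sense, 30, replace = TRUE)
  aln <- codon_alignment(rbind(t1 = s, t2 = s, t3 = s, t4 = s))
  tr <- fixture_tree(4, 0.1)
  fit <- fit_m0(tr, aln)
  expect_lt(max(fit$tree$edge.length), 1e-6)
})

test_that("fixed-sites fit separates planted partition omegas", {
  tr <- simulate_tree(6, 0.1, seed = 3)
  sim <- simulate_codon_alignment(tr, c(a = 0.05, b = 0.5),
                                  c(a = 300L, b = 300L), kappa = 4, seed = 9)
  parts <- list(a = subset_alignment(sim$alignment,
                                     which(sim$partition == "a")),
                b = subset_alignment(sim$alignment,
                                     which(sim$partition == "b")))
  fs <- fit_fixed_sites(tr, parts)
  expect_lt(fs$omegas[["a"]], fs$omegas[["b"]])
  expect_gt(fs$omegas[["a"]], 0.01)
  expect_lt(fs$omegas[["a"]], 0.12)
  expect_gt(fs$omegas[["b"]], 0.3)
  expect_lt(fs$omegas[["b"]], 0.75)
  expect_true(all(fs$se_omegas[c("a", "b")] > 0))
  # identical data in both partitions -> equal omegas
  fs2 <- fit_fixed_sites(tr, list(x = parts$a, y = parts$a))
  expect_equal(unname(fs2$omegas[["x"]]), unname(fs2$omegas[["y"]]),
               tolerance = 1e-3)
  # empty partitions skipped with warning; all-empty is an error
  expect_warning(fs3 <- fit_fixed_sites(tr, list(a = parts$a, z = NULL)),
                 "empty")
  expect_true(is.na(fs3$omegas[["z"]]))
  expect_error(suppressWarnings(fit_fixed_sites(tr, list(z = NULL))),
               "empty")
})

test_that("the M1a/M2a LRT is exact at the nested boundary and orderly", {
  tr <- simulate_tree(5, 0.15, seed = 41)
  sim <- simulate_codon_alignment(tr, c(a = 0.3, b = 1),
                                  c(a = 100L, b = 50L), kappa = 4,
                                  seed = 42, scale = "common")
  lrt <- fit_site_models_lrt(tr, sim$alignment, n_starts = 2)
  expect_gte(lrt$stat, 0)
  expect_gte(lrt$lnL_m2a, lrt$lnL_m1a - 1e-6)
  expect_equal(lrt$p, pchisq(lrt$stat, 2, lower.tail = FALSE))
  expect_false(lrt$optimizer_failure)
  expect_equal(sum(lrt$m2a$p), 1, tolerance = 1e-8)
  # taxon order invariance
  aln_r <- codon_alignment(sim$alignment$codons[c(3, 5, 1, 2, 4), ],
                           code = sim$alignment$code)
  lrt2 <- fit_site_models_lrt(tr, aln_r, n_starts = 2)
  expect_equal(lrt2$stat, lrt$stat, tolerance = 1e-3)
})

test_that("positive selection is detected when planted strongly", {
  tr <- simulate_tree(6, 0.25, seed = 21)
  sim <- simulate_codon_alignment(tr, c(neu = 0.2, pos = 8),
                                  c(neu = 240L, pos = 60L), kappa = 4,
                                  seed = 22, scale = "common")
  lrt <- fit_site_models_lrt(tr, sim$alignment)
  expect_lt(lrt$p, 0.01)
  expect_gt(lrt$m2a$omega2, 2)
})
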