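# Pairwise dN/dS, Sigma-dN accumulation, interaction ratio.

test_that("identical sequences give zero divergence", {
  s <- c("ATG", "TTT", "GCA")
  p <- pairwise_dn(s, s, method = "ng86")
  expect_equal(p$dN, 0)
  expect_equal(p$dS, 0)
  expect_equal(p$N_sites + p$S_sites, 3 * p$usable_codons)
})

test_that("the single-codon TTT/TTA example reproduces hand-enumerated sites", {
  # universal code: S(TTT) = 1/3, S(TTA) = 2/3; one nonsynonymous
  # difference; N = (8/3 + 7/3)/2 = 2.5, so pN = 1/2.5 = 0.4
  p <- pairwise_dn("TTT", "TTA", code = "universal", method = "ng86")
  expect_equal(p$Nd, 1)
  expect_equal(p$Sd, 0)
  expect_equal(p$N_sites, 2.5)
  expect_equal(p$pN, 0.4)
  expect_equal(p$dN, -0.75 * log(1 - 4 * 0.4 / 3))
  s <- codon_sites("universal")
  expect_equal(unname(s["TTT", "S"]), 1 / 3)
  expect_equal(unname(s["TTA", "S"]), 2 / 3)
})

test_that("dN and dS are symmetric in the two sequences", {
  set.seed(3)
  gcv <- genetic_code("vertebrate_mito")
  for (rep in 1:5) {
    a <- sample(gcv$sense, 30, replace = TRUE)
    b <- sample(gcv$sense, 30, replace = TRUE)
    pab <- pairwise_dn(a, b)
    pba <- pairwise_dn(b, a)
    expect_equal(pab$dN, pba$dN)
    expect_equal(pab$dS, pba$dS)
    expect_equal(pab$N_sites + pab$S_sites, 3 * pab$usable_codons)
  }
})

test_that("one nonsynonymous nucleotide difference gives Sd = 0, Nd = 1", {
  # GCA (Ala) vs CCA (Pro): single transversion, nonsynonymous
  p <- pairwise_dn("GCA", "CCA", method = "ng86")
  expect_equal(p$Sd, 0)
  expect_equal(p$Nd, 1)
})

test_that("gapped codons are skipped pairwise and saturation is flagged", {
  p <- pairwise_dn(c("ATG", NA, "GCA"), c("ATG", "TTT", NA))
  expect_equal(p$usable_codons, 1)
  expect_true(is.na(pairwise_dn(character(0), character(0))$dN))
  # saturated: every position differs nonsynonymously
  many_a <- rep("AAA", 5)  # Lys
  many_c <- rep("CCC", 5)  # Pro
  ps <- pairwise_dn(many_a, many_c, method = "ng86")
  expect_true(is.na(ps$dN) || ps$pN < 0.75)
})

test_that("sum_dn equals the explicit sum over pairs and is order-invariant", {
  tr <- simulate_tree(3, 0.15, seed = 1)
  sim <- simulate_codon_alignment(tr, c(a = 0.4), c(a = 40L), seed = 2)
  aln <- sim$alignment
  s <- sum_dn(aln, method = "ng86", boot_reps = 0)
  pairs <- combn(3, 2)
  tot <- sum(apply(pairs, 2, function(ij)
    pairwise_dn(aln$codons[ij[1], ], aln$codons[ij[2], ],
                method = "ng86")$dN))
  expect_equal(s$sum_dn, tot, tolerance = 1e-12)
  # taxon reordering
  aln_r <- codon_alignment(aln$codons[c(3, 1, 2), ], code = aln$code)
  expect_equal(sum_dn(aln_r, method = "ng86", boot_reps = 0)$sum_dn,
               s$sum_dn, tolerance = 1e-12)
  # column reordering
  aln_c <- subset_alignment(aln, rev(seq_len(aln$n_col)))
  expect_equal(sum_dn(aln_c, method = "ng86", boot_reps = 0)$sum_dn,
               s$sum_dn, tolerance = 1e-12)
  # two taxa: sum equals the single pairwise value
  two <- codon_alignment(aln$codons[1:2, ], code = aln$code)
  expect_equal(sum_dn(two, method = "ng86", boot_reps = 0)$sum_dn,
               pairwise_dn(aln$codons[1, ], aln$codons[2, ],
                           method = "ng86")$dN)
  # all-identical taxa
  same <- codon_alignment(rbind(t1 = aln$codons[1, ], t2 = aln$codons[1, ],
                                t3 = aln$codons[1, ]), code = aln$code)
  expect_equal(sum_dn(same, boot_reps = 0)$sum_dn, 0)
  expect_error(sum_dn(codon_alignment(aln$codons[1, , drop = FALSE],
                                      code = aln$code)), "taxa")
})

test_that("under neutral simulation NG86 dN/dS is near 1", {
  tr <- fixture_pair_tree(0.8)
  sim <- simulate_codon_alignment(tr, c(a = 1), c(a = 2000L), kappa = 2,
                                  seed = 9)
  p <- pairwise_dn(sim$alignment$codons[1, ], sim$alignment$codons[2, ],
                   method = "ng86")
  expect_gt(p$dN / p$dS, 0.8)
  expect_lt(p$dN / p$dS, 1.25)
})

test_that("pairwise estimates track the planted omega ordering", {
  tr <- fixture_pair_tree(0.6)
  sim <- simulate_codon_alignment(tr, c(lo = 0.1, hi = 0.8),
                                  c(lo = 400L, hi = 400L), seed = 5)
  aln <- sim$alignment
  lo <- subset_alignment(aln, which(sim$partition == "lo"))
  hi <- subset_alignment(aln, which(sim$partition == "hi"))
  p_lo <- pairwise_dn(lo$codons[1, ], lo$codons[2, ])
  p_hi <- pairwise_dn(hi$codons[1, ], hi$codons[2, ])
  expect_lt(p_lo$dN / p_lo$dS, p_hi$dN / p_hi$dS)
})

test_that("interaction ratio contracts hold", {
  expect_equal(interaction_ratio(2.5, 2.5)$ratio, 1)
  r <- interaction_ratio(3, 2)
  expect_equal(r$ratio, 1.5)
  expect_true(r$defined)
  r0 <- interaction_ratio(1, 0)
  expect_false(r0$defined)
  expect_true(is.na(r0$ratio))
})

test_that("column bootstrap SE is reproducible and plausible", {
  tr <- simulate_tree(4, 0.2, seed = 6)
  sim <- simulate_codon_alignment(tr, c(a = 0.5), c(a = 80L), seed = 7)
  s1 <- sum_dn(sim$alignment, boot_reps = 100, seed = 42)
  s2 <- sum_dn(sim$alignment, boot_reps = 100, seed = 42)
  expect_equal(s1$se_sum_dn, s2$se_sum_dn)
  expect_gt(s1$se_sum_dn, 0)
  expect_lt(s1$se_sum_dn, s1$sum_dn)
})
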