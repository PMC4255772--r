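# Codon alignment IO, reference mapping, class partitioning.

test_that("read_codon_alignment validates shape and flags stop codons", {
  p <- write_fixture_fasta(c(t1 = "ATGTTTGCA", t2 = "ATGTTCGCA",
                             t3 = "ATGTTAGCC"))
  aln <- read_codon_alignment(p)
  expect_equal(aln$n_col, 3)
  expect_equal(aln$taxa, c("t1", "t2", "t3"))

  # length not divisible by 3
  p2 <- write_fixture_fasta(c(t1 = "ATGT", t2 = "ATGA"))
  expect_error(read_codon_alignment(p2), "divisible")

  # duplicate taxa
  p3 <- write_fixture_fasta(c(x = "ATG", x = "ATG"))
  expect_error(read_codon_alignment(p3), "duplicate")

  # internal TAA is a stop under the vertebrate mito code: flagged + masked
  p4 <- write_fixture_fasta(c(t1 = "ATGTAAGCA", t2 = "ATGTTCGCA"))
  aln4 <- read_codon_alignment(p4, code = "vertebrate_mito")
  expect_equal(nrow(aln4$flagged_stops), 1)
  expect_equal(aln4$flagged_stops$codon, "TAA")
  expect_true(is.na(aln4$codons["t1", 2]))
})

test_that("AGA is a stop under the mito code but sense under the universal", {
  p <- write_fixture_fasta(c(t1 = "ATGAGAGCA", t2 = "ATGAGGGCA"))
  mito <- read_codon_alignment(p, code = "vertebrate_mito")
  expect_equal(sort(mito$flagged_stops$codon), c("AGA", "AGG"))
  uni <- read_codon_alignment(p, code = "universal")
  expect_equal(nrow(uni$flagged_stops), 0)
  expect_equal(unname(uni$codons["t1", 2]), "AGA")
  # cross-check against the published code tables
  expect_equal(unname(Biostrings::getGeneticCode("2")[["AGA"]]), "*")
  expect_equal(unname(Biostrings::getGeneticCode("1")[["AGA"]]), "R")
})

test_that("reference mapping skips gapped reference columns", {
  # ungapped reference: identity map
  p <- write_fixture_fasta(c(ref = "ATGTTTGCAAAA", o = "ATGTTCGCAAAG"))
  aln <- read_codon_alignment(p)
  rm1 <- map_alignment_to_reference(aln, "ref", "A", 1)
  expect_equal(rm1$column, 1:4)
  expect_equal(rm1$resno, 1:4)

  # reference gapped at column 2 of 4
  p2 <- write_fixture_fasta(c(ref = "ATG---GCAAAA", o = "ATGTTCGCAAAG"))
  aln2 <- read_codon_alignment(p2)
  rm2 <- map_alignment_to_reference(aln2, "ref", "A", 1)
  expect_equal(rm2$column, c(1, 3, 4))
  expect_equal(rm2$resno, 1:3)
  expect_equal(attr(rm2, "n_unmapped"), 1)

  expect_error(map_alignment_to_reference(aln2, "zz", "A"), "zz")
})

test_that("random gap patterns map like an independent scan-counting oracle", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 12
    gaps <- sort(sample.int(n, sample(0:5, 1)))
    codons <- rep("ATG", n)
    codons[gaps] <- "---"
    seqs <- c(ref = paste(codons, collapse = ""),
              o = paste(rep("ATG", n), collapse = ""))
    aln <- read_codon_alignment(write_fixture_fasta(seqs))
    rm <- map_alignment_to_reference(aln, "ref", "A", 7)
    # oracle: linear scan counting ungapped reference codons
    expect_col <- setdiff(seq_len(n), gaps)
    expect_equal(rm$column, expect_col)
    expect_equal(rm$resno, 7 + seq_along(expect_col) - 1)
  }
})

test_that("partitioning splits columns by class and conserves them", {
  m <- fixture_codon_matrix()
  aln <- codon_alignment(m)
  rm <- map_alignment_to_reference(aln, "t1", "A", 1)
  labels <- data.frame(
    chain = "A", resno = 1:4, insert = "", resid = "GLY",
    key = paste0("A:", 1:4),
    site_class = c("MT_NU_CONTACT", "EXPOSED_NONCONTACT",
                   "EXPOSED_NONCONTACT", "BURIED_NONCONTACT"),
    interface = c(NA, TRUE, FALSE, NA), stringsAsFactors = FALSE)
  part <- partition_alignment(aln, rm, labels)
  expect_setequal(names(part$classes),
                  c("MT_NU_CONTACT", "EXPOSED_NONCONTACT",
                    "BURIED_NONCONTACT"))
  expect_equal(part$classes$EXPOSED_NONCONTACT, 2:3)
  # column conservation
  expect_equal(sum(lengths(part$classes)), nrow(rm))
  # taxon order preserved
  expect_equal(part$alignments$MT_NU_CONTACT$taxa, aln$taxa)
  # interface sub-split
  part2 <- partition_alignment(aln, rm, labels, split_interface = TRUE)
  expect_equal(part2$classes$EXPOSED_INTERFACE, 2L)
  expect_equal(part2$classes$EXPOSED_NONINTERFACE, 3L)
  # missing labels are an error listing residues
  expect_error(partition_alignment(aln, rm, labels[-2, ]), "A:2")
})

test_that("single-class partition restricted to mapped columns, identity", {
  m <- fixture_codon_matrix()
  aln <- codon_alignment(m)
  rm <- map_alignment_to_reference(aln, "t1", "A", 1)
  labels <- data.frame(chain = "A", resno = 1:4, insert = "", resid = "GLY",
                       key = paste0("A:", 1:4),
                       site_class = "EXPOSED_NONCONTACT",
                       interface = FALSE, stringsAsFactors = FALSE)
  part <- partition_alignment(aln, rm, labels)
  expect_equal(part$alignments$EXPOSED_NONCONTACT$codons, aln$codons)
})

test_that("sub-alignments round-trip through FASTA exactly", {
  m <- fixture_codon_matrix()
  m[2, 3] <- NA  # masked codon becomes --- on write
  aln <- codon_alignment(m)
  p <- tempfile(fileext = ".fasta")
  write_codon_alignment(aln, p)
  back <- read_codon_alignment(p)
  expect_equal(back$codons, aln$codons)
  expect_equal(back$taxa, aln$taxa)
})
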