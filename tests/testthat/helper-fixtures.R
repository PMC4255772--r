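# Shared fixtures built in code: tiny PDB files, small alignments, trees.

# Write a minimal PDB with explicit atom records.
# atoms: data frame with type, eleno, elety, resid, chain, resno, x, y, z
write_fixture_pdb <- function(atoms, path = tempfile(fileext = ".pdb"),
                              alt = NULL, occ = NULL) {
  if (is.null(alt)) alt <- rep(" ", nrow(atoms))
  if (is.null(occ)) occ <- rep(1, nrow(atoms))
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            atoms$type[i], atoms$eleno[i],
            substr(paste0(" ", atoms$elety[i], "   "), 1, 4), alt[i],
            atoms$resid[i], atoms$chain[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], occ[i], 0,
            substr(atoms$elety[i], 1, 1))
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# Two-chain, six-residue fixture: chains A (4 residues) and B (2 residues),
# one designed A-B contact at 3 Angstrom (residues A3 and B1).
fixture_two_chain <- function() {
  atoms <- data.frame(
    type = "ATOM", eleno = 1:6, elety = "CA", resid = "ALA",
    chain = c("A", "A", "A", "A", "B", "B"),
    resno = c(1, 2, 3, 4, 1, 2),
    x = c(0, 9, 18, 27, 18, 27),
    y = c(0, 0, 0, 0, 3, 30),
    z = 0, stringsAsFactors = FALSE)
  write_fixture_pdb(atoms)
}

# Write an aligned FASTA from a named character vector of sequences.
write_fixture_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

# Small fixed codon alignment matrix (3 taxa x 4 columns, mito-safe codons).
fixture_codon_matrix <- function() {
  m <- rbind(
    t1 = c("ATG", "TTT", "GCA", "AAA"),
    t2 = c("ATG", "TTC", "GCA", "AAG"),
    t3 = c("ATG", "TTA", "GCC", "AAA"))
  m
}

# Two-taxon "tree": a single path between the tips, split over two edges.
fixture_pair_tree <- function(bl = 0.2) {
  structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                 edge.length = c(bl / 2, bl / 2),
                 tip.label = c("t1", "t2"), Nnode = 1L),
            class = "phylo", order = "cladewise")
}

# Fixed small tree over n tips with deterministic branch lengths.
fixture_tree <- function(n = 4, bl = 0.1) {
  tr <- ape::unroot(ape::stree(n, type = "left"))
  if (is.null(tr$edge.length)) tr$edge.length <- rep(bl, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
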