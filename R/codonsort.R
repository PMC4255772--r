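# Codon alignments: IO, reference-structure mapping, class partitioning.

#' Read and validate a codon alignment from FASTA
#'
#' Sequences must be aligned, of equal length divisible by three. Codons are
#' the unit of analysis: a codon containing any gap character is treated as
#' fully gapped, and codons containing ambiguity codes are masked. Internal
#' stop codons under the requested genetic code are reported (and masked)
#' rather than fatal, since terminal stops and alignment artefacts occur in
#' real data.
#'
#' @param path FASTA file of aligned nucleotide sequences.
#' @param code Genetic code name (see [genetic_code()]).
#' @return A `codon_alignment`: list with `taxa`, `codons` (taxa x columns
#'   character matrix, `NA` for gapped/ambiguous/stop codons), `n_col`,
#'   `code`, and `flagged_stops` (data frame taxon/column of masked stops).
#' @export
read_codon_alignment <- function(path, code = "vertebrate_mito") {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  taxa <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(taxa)) stop("duplicate taxon identifiers in ", path)
  mat <- as.matrix(seqs)  # errors if unequal lengths
  codon_alignment_from_matrix(mat, taxa, code)
}

codon_alignment_from_matrix <- function(mat, taxa, code) {
  if (ncol(mat) %% 3L != 0L)
    stop("alignment length ", ncol(mat), " is not divisible by 3")
  n_col <- ncol(mat) %/% 3L
  gc <- genetic_code(code)
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  bad <- !(mat %in% c("A", "C", "G", "T", "-", ".", "N")) &
    !(mat %in% strsplit("RYSWKMBDHV", "")[[1]])
  if (any(bad))
    stop("non-IUPAC characters in alignment: ",
         paste(unique(mat[bad]), collapse = ", "))
  codons <- matrix(NA_character_, nrow(mat), n_col,
                   dimnames = list(taxa, NULL))
  gapped <- matrix(FALSE, nrow(mat), n_col, dimnames = list(taxa, NULL))
  flagged <- list()
  for (k in seq_len(n_col)) {
    block <- mat[, (3 * k - 2):(3 * k), drop = FALSE]
    cod <- paste0(block[, 1], block[, 2], block[, 3])
    clean <- grepl("^[ACGT]{3}$", cod)
    # a codon touching a gap character is treated as fully gapped
    gapped[, k] <- grepl("[-.]", cod)
    is_stop <- clean & cod %in% gc$stops
    if (any(is_stop))
      flagged[[length(flagged) + 1L]] <-
        data.frame(taxon = taxa[is_stop], column = k, codon = cod[is_stop],
                   stringsAsFactors = FALSE)
    cod[!clean | is_stop] <- NA_character_
    codons[, k] <- cod
  }
  structure(list(
    taxa = taxa, codons = codons, gapped = gapped, n_col = n_col, code = code,
    flagged_stops = if (length(flagged)) do.call(rbind, flagged) else
      data.frame(taxon = character(), column = integer(), codon = character())
  ), class = "codon_alignment")
}

#' Build a codon alignment from a character matrix of codons
#'
#' Convenience constructor used by the simulator and tests.
#'
#' @param codons Character matrix (taxa x columns) of 3-letter codons or NA.
#' @param code Genetic code name.
#' @return A `codon_alignment`.
#' @export
codon_alignment <- function(codons, code = "vertebrate_mito") {
  stopifnot(is.matrix(codons), !is.null(rownames(codons)))
  structure(list(taxa = rownames(codons), codons = codons,
                 gapped = is.na(codons),
                 n_col = ncol(codons), code = code,
                 flagged_stops = data.frame(taxon = character(),
                                            column = integer(),
                                            codon = character())),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa x", x$n_col,
      "codon columns (", x$code, "code )\n")
  invisible(x)
}

#' Write a codon alignment to FASTA
#'
#' Masked codons (`NA`) are written as `---`.
#'
#' @param aln A `codon_alignment`.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  m <- aln$codons
  m[is.na(m)] <- "---"
  seqs <- apply(m, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(seqs, aln$taxa)), path)
  invisible(path)
}

#' Restrict a codon alignment to a set of columns
#' @param aln A `codon_alignment`.
#' @param cols Integer vector of column indices.
#' @return A `codon_alignment` over those columns (taxon order preserved).
#' @export
subset_alignment <- function(aln, cols) {
  codon_alignment(aln$codons[, cols, drop = FALSE], code = aln$code)
}

#' Map alignment columns to reference-structure residue numbers
#'
#' The k-th reference-ungapped column is assigned residue number
#' `first_residue_number + k - 1` on `chain_id`. Columns where the
#' reference taxon is gapped receive no mapping (they cannot be
#' structurally labelled).
#'
#' @param aln A `codon_alignment`.
#' @param ref_taxon Reference taxon identifier (must be in the alignment).
#' @param chain_id Structure chain the reference sequence corresponds to.
#' @param first_residue_number Residue number of the first reference codon.
#' @return A `reference_map`: data frame with `column`, `chain`, `resno`,
#'   `key`, one row per mapped column, plus attributes `ref_taxon` and
#'   `n_unmapped`.
#' @export
map_alignment_to_reference <- function(aln, ref_taxon, chain_id,
                                       first_residue_number = 1L) {
  if (!ref_taxon %in% aln$taxa) stop("reference taxon not found: ", ref_taxon)
  # a reference codon occupies a residue position unless gapped; masked
  # codons (ambiguity, stop) still advance the residue counter
  ungapped <- which(!aln$gapped[ref_taxon, ])
  resno <- first_residue_number + seq_along(ungapped) - 1L
  out <- data.frame(column = ungapped, chain = chain_id, resno = resno,
                    key = res_key(chain_id, resno, ""),
                    stringsAsFactors = FALSE)
  attr(out, "ref_taxon") <- ref_taxon
  attr(out, "n_unmapped") <- aln$n_col - length(ungapped)
  class(out) <- c("reference_map", "data.frame")
  out
}

#' Partition alignment columns into structural site classes
#'
#' Joins the column -> residue map with per-residue structural labels and
#' splits the alignment into one sub-alignment per class. Columns where the
#' reference is gapped are reported under `UNMAPPED` and excluded from every
#' class.
#'
#' @param aln A `codon_alignment`.
#' @param refmap A `reference_map` from [map_alignment_to_reference()].
#' @param labels A `site_labels` data frame covering all mapped residues.
#' @param split_interface If `TRUE`, `EXPOSED_NONCONTACT` is further split
#'   into `EXPOSED_INTERFACE` / `EXPOSED_NONINTERFACE` by the interface flag.
#' @return A `site_partition`: list with `classes` (named list class ->
#'   integer column vector), `alignments` (named list class ->
#'   `codon_alignment`, absent classes map to `NULL`), `column_class`
#'   (character vector over all columns, `UNMAPPED` where applicable).
#' @export
partition_alignment <- function(aln, refmap, labels, split_interface = FALSE) {
  lab <- setNames(labels$site_class, labels$key)
  if (split_interface) {
    en <- labels$site_class == "EXPOSED_NONCONTACT"
    lab[labels$key[en]] <- ifelse(labels$interface[en],
                                  "EXPOSED_INTERFACE", "EXPOSED_NONINTERFACE")
  }
  missing <- setdiff(refmap$key, names(lab))
  if (length(missing))
    stop("mapped residues lack structural labels: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ...")
  column_class <- rep("UNMAPPED", aln$n_col)
  column_class[refmap$column] <- unname(lab[refmap$key])
  cls_names <- setdiff(unique(column_class), "UNMAPPED")
  classes <- lapply(setNames(cls_names, cls_names),
                    function(cl) which(column_class == cl))
  alignments <- lapply(classes, function(cols)
    if (length(cols)) subset_alignment(aln, cols) else NULL)
  structure(list(classes = classes, alignments = alignments,
                 column_class = column_class),
            class = "site_partition")
}

#' Write a column -> class map as TSV
#' @param part A `site_partition`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_partition_tsv <- function(part, path) {
  df <- data.frame(column = seq_along(part$column_class),
                   class = part$column_class)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
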