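# In-frame codon alignments keyed by taxon-role labels. Sequences are stored
# both as character strings and as a matrix of codon indices (1..61 over the
# sense codons, NA for gap/missing codons).

#' Construct a codon alignment
#'
#' @param sequences Named character vector of nucleotide sequences of equal
#'   length divisible by 3. Gap codons are written `---`; any codon containing
#'   `-` or `N` is treated as missing data. Stop codons are rejected.
#' @return An object of class `codon_alignment` with elements `labels`,
#'   `sequences`, `index` (sequence x column codon-index matrix) and
#'   `n_codons`.
#' @examples
#' aln <- codon_alignment(c(A = "ATGAAA", B = "ATG---"))
#' aln$n_codons
#' @export
codon_alignment <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be a named character vector")
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence labels")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1)
    stop("all sequences must have equal length")
  if (lens[1] %% 3 != 0)
    stop("sequence length must be divisible by 3")
  n_codons <- lens[1] %/% 3
  if (n_codons < 1) stop("alignment must contain at least one codon column")
  seqs <- toupper(sequences)
  idx <- matrix(NA_integer_, nrow = length(seqs), ncol = n_codons,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    cods <- substring(seqs[i], seq(1, lens[1], 3), seq(3, lens[1], 3))
    idx[i, ] <- codon_indices(cods, context = names(seqs)[i])
  }
  if (all(is.na(idx))) stop("alignment contains only gap codons")
  structure(list(labels = names(seqs),
                 sequences = seqs,
                 index = idx,
                 n_codons = n_codons),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d sequences x %d codon columns\n",
              length(x$labels), x$n_codons))
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# index matrix -> sequence strings
codons_to_string <- function(idx_row) {
  cods <- ifelse(is.na(idx_row), "---", sense_codons()[idx_row])
  paste0(cods, collapse = "")
}

#' Read a codon alignment from FASTA
#'
#' @param path Path to a FASTA file of aligned, in-frame nucleotide sequences.
#' @return A [codon_alignment()].
#' @export
read_codon_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(as.character(ss), names(ss)))
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "codon_alignment"))
  ss <- Biostrings::BStringSet(aln$sequences)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Reverse-translate a protein alignment onto its coding sequences
#'
#' Threads each ungapped coding sequence back through its aligned protein,
#' replacing every amino acid by its source codon and every protein gap by a
#' gap codon, producing the in-frame multiple nucleotide alignment used for
#' codon-model fitting.
#'
#' @param protein_alignment Named character vector of aligned protein
#'   sequences (gap character `-`).
#' @param cds_sequences Named character vector of ungapped coding sequences;
#'   each must translate exactly to its ungapped protein (a trailing stop
#'   codon is allowed and dropped).
#' @return A [codon_alignment()].
#' @examples
#' reverse_translate(c(x = "M-K", y = "MQK"),
#'                   c(x = "ATGAAA", y = "ATGCAAAAA"))
#' @export
reverse_translate <- function(protein_alignment, cds_sequences) {
  if (!setequal(names(protein_alignment), names(cds_sequences)))
    stop("protein and CDS labels do not match")
  out <- vapply(names(protein_alignment), function(nm) {
    prot <- toupper(protein_alignment[[nm]])
    cds <- toupper(cds_sequences[[nm]])
    aas <- strsplit(prot, "")[[1]]
    n_aa <- sum(aas != "-")
    if (nchar(cds) %% 3 != 0)
      stop(sprintf("CDS of '%s' has length %d, not divisible by 3", nm, nchar(cds)))
    cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    # trailing stop codon tolerated
    if (length(cods) == n_aa + 1 && cods[length(cods)] %in% c("TAA", "TAG", "TGA"))
      cods <- cods[-length(cods)]
    if (length(cods) != n_aa)
      stop(sprintf("CDS of '%s' has %d codons but protein has %d residues",
                   nm, length(cods), n_aa))
    translated <- codon_amino_acids()[codon_indices(cods, context = nm)]
    mism <- which(translated != aas[aas != "-"])
    if (length(mism))
      stop(sprintf("CDS of '%s' does not translate to its protein at residue %d (%s vs %s)",
                   nm, mism[1], translated[mism[1]], aas[aas != "-"][mism[1]]))
    filled <- character(length(aas))
    filled[aas == "-"] <- "---"
    filled[aas != "-"] <- cods
    paste0(filled, collapse = "")
  }, character(1))
  codon_alignment(out)
}
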