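#' @useDynLib dupaccel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Standard genetic code over the 61 sense codons. Stop codons (TAA, TAG, TGA)
# are excluded from the state space and rejected at parse time.

.nt <- c("T", "C", "A", "G")

.codon_env <- new.env(parent = emptyenv())

.build_code_tables <- function() {
  # third position varies fastest: TTT, TTC, TTA, TTG, TCT, ...
  grid <- expand.grid(p3 = .nt, p2 = .nt, p1 = .nt,
                      stringsAsFactors = FALSE)[, 3:1]
  all64 <- paste0(grid$p1, grid$p2, grid$p3)
  aa64 <- vapply(all64, function(cd) {
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE))
  }, character(1))
  sense <- all64[aa64 != "*"]
  aa <- unname(aa64[aa64 != "*"])
  stopifnot(length(sense) == 61L)

  n <- length(sense)
  cm <- do.call(rbind, strsplit(sense, ""))  # 61 x 3 nucleotide matrix

  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(cm[, p], cm[, p], "!=")
  single <- ndiff == 1L

  purine <- function(x) x %in% c("A", "G")
  is_ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    d <- outer(cm[, p], cm[, p], "!=") & single
    same_class <- outer(purine(cm[, p]), purine(cm[, p]), "==")
    is_ts[d & same_class] <- TRUE
  }
  is_syn <- outer(aa, aa, "==")

  assign("codons", sense, envir = .codon_env)
  assign("aa", aa, envir = .codon_env)
  assign("codon_nt", cm, envir = .codon_env)
  assign("single_step", single, envir = .codon_env)
  assign("is_transition", is_ts & single, envir = .codon_env)
  assign("is_synonymous", is_syn & single, envir = .codon_env)
  invisible(NULL)
}

.code <- function(what) {
  if (!exists("codons", envir = .codon_env)) .build_code_tables()
  get(what, envir = .codon_env)
}

#' Sense codons of the standard genetic code
#'
#' Returns the 61 sense codons in the fixed internal order used throughout the
#' package (TTT, TTC, ... with the third position varying fastest; stop codons
#' TAA, TAG, TGA removed).
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() .code("codons")

#' Amino acid encoded by each sense codon
#'
#' @return Character vector of length 61, single-letter amino-acid codes,
#'   parallel to [sense_codons()].
#' @export
codon_amino_acids <- function() .code("aa")

# Map codon strings to indices in 1..61; NA for gap/ambiguous codons;
# error on stop codons.
codon_indices <- function(codons, context = "sequence") {
  idx <- match(codons, .code("codons"))
  unknown <- is.na(idx)
  if (any(unknown)) {
    bad <- codons[unknown]
    gapish <- grepl("[-N.]", bad) | bad == "---"
    stops <- bad %in% c("TAA", "TAG", "TGA")
    if (any(stops)) {
      stop(sprintf("stop codon %s at codon position %d in %s",
                   bad[stops][1], which(unknown)[stops][1], context))
    }
    if (!all(gapish)) {
      stop(sprintf("unrecognised codon '%s' at codon position %d in %s",
                   bad[!gapish][1], which(unknown)[!gapish][1], context))
    }
  }
  idx
}
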