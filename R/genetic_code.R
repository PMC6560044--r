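## Standard genetic code services: translation, synonymy, site degeneracy.
## All conservation and codon-usage statistics sit on top of this layer.
## Only the standard nuclear code is supported (the analysis targets
## vertebrate nuclear genes); the table is a fixed internal constant so the
## degeneracy classification can be precomputed once at load time.

BASES <- c("A", "C", "G", "T")

# Codon -> one-letter amino acid, standard code, DNA alphabet ("*" = stop).
.code_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.code_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    .code_env$tab <- stats::setNames(as.character(gc), names(gc))
  }
  .code_env$tab
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons (DNA alphabet, uppercase).
#' @export
sense_codons <- function() {
  tab <- .genetic_code()
  names(tab)[tab != "*"]
}

.check_cds <- function(cds) {
  if (!is.character(cds) || length(cds) != 1L || is.na(cds) || nchar(cds) == 0L)
    stop("cds must be a single non-empty string")
  cds <- toupper(cds)
  if (grepl("U", cds, fixed = TRUE)) {
    warning("RNA alphabet detected; normalizing U -> T")
    cds <- gsub("U", "T", cds, fixed = TRUE)
  }
  if (grepl("[^ACGT]", cds))
    stop("cds contains non-ACGT characters (ambiguity codes are rejected)")
  if (nchar(cds) %% 3L != 0L)
    stop("cds length is not divisible by 3")
  cds
}

#' Split a CDS into codons
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Character vector of codons in order.
#' @export
split_codons <- function(cds) {
  cds <- .check_cds(cds)
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a coding sequence
#'
#' Translates under the standard genetic code. A terminal stop codon is
#' allowed and dropped from the protein (it stays visible to codon-level
#' bookkeeping elsewhere); an internal stop is an error, as is any non-ACGT
#' character or a length not divisible by 3.
#'
#' @param cds Nucleotide string (DNA alphabet; U is normalized to T with a
#'   warning).
#' @return One-letter amino-acid string.
#' @examples
#' translate_cds("ATGGCT")  # "MA"
#' translate_cds("ATGTAA")  # "M"
#' @export
translate_cds <- function(cds) {
  codons <- split_codons(cds)
  aas <- .genetic_code()[codons]
  stops <- which(aas == "*")
  if (length(stops) > 0L) {
    if (any(stops < length(aas)))
      stop("internal stop codon at codon ", stops[stops < length(aas)][1L])
    aas <- aas[-length(aas)]
  }
  paste0(aas, collapse = "")
}

#' Codon-site degeneracy classification
#'
#' For a sense codon and a position 1-3, the fold is the number of
#' nucleotides (including the observed one) that leave the encoded amino acid
#' unchanged when substituted at that position. A fourfold degenerate site is
#' one where any possible nucleotide substitution is synonymous (fold 4);
#' these third positions are free of selection for amino-acid maintenance.
#'
#' @param codon Sense codon (3 characters, ACGT).
#' @param position Integer 1, 2 or 3.
#' @return List with `codon`, `position`, `fold`, `is_fourfold`.
#' @examples
#' degeneracy("GCT", 3)  # fold 4 (alanine)
#' degeneracy("AAT", 3)  # fold 2 (AAT/AAC Asn vs AAA/AAG Lys)
#' @export
degeneracy <- function(codon, position) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("invalid codon: ", codon)
  if (!position %in% 1:3) stop("position must be 1, 2 or 3")
  tab <- .genetic_code()
  aa <- tab[[codon]]
  if (aa == "*") stop("stop codon has no degeneracy class: ", codon)
  variants <- vapply(BASES, function(b) {
    v <- codon
    substr(v, position, position) <- b
    tab[[v]]
  }, character(1))
  fold <- sum(variants == aa)
  list(codon = codon, position = as.integer(position), fold = fold,
       is_fourfold = fold == 4L)
}

#' Synonymous codons of an amino acid
#'
#' @param amino_acid One-letter code of a standard amino acid (stop excluded).
#' @return Character vector of its codons.
#' @export
synonymous_codons <- function(amino_acid) {
  if (!is.character(amino_acid) || length(amino_acid) != 1L ||
      nchar(amino_acid) != 1L)
    stop("amino_acid must be a single one-letter code")
  amino_acid <- toupper(amino_acid)
  tab <- .genetic_code()
  if (amino_acid == "*") stop("stop is not an amino acid")
  hits <- names(tab)[tab == amino_acid]
  if (length(hits) == 0L) stop("unknown amino-acid code: ", amino_acid)
  hits
}

# fold at position 3 for every sense codon, precomputed (used in hot loops)
.fold3_table <- function() {
  if (is.null(.code_env$fold3)) {
    sc <- sense_codons()
    .code_env$fold3 <- stats::setNames(
      vapply(sc, function(cd) degeneracy(cd, 3)$fold, integer(1)), sc)
  }
  .code_env$fold3
}
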