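## Pairwise global alignment (affine-gap Needleman-Wunsch, compiled), the
## gap-excluded identity score used throughout (CDS, protein, 3'UTR), and
## codon-aware multiple alignment of coding sequences that share a protein.

.aln_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.aln_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .aln_env$blosum62 <- e$BLOSUM62
  }
  .aln_env$blosum62
}

#' Default alignment scoring
#'
#' Nucleotide defaults: match +2, mismatch -1, gap_open -5, gap_extend -1
#' (a gap of length k scores gap_open + k * gap_extend). Protein alignments
#' use BLOSUM62 with gap_open -10, gap_extend -1. Gap-excluded identity is
#' robust to reasonable variations of these choices.
#'
#' @param type `"dna"` or `"protein"`.
#' @return List with `matrix` (substitution matrix), `gap_open`, `gap_extend`.
#' @export
default_scoring <- function(type = c("dna", "protein")) {
  type <- match.arg(type)
  if (type == "dna") {
    m <- matrix(-1, 4, 4, dimnames = list(BASES, BASES))
    diag(m) <- 2
    list(matrix = m, gap_open = -5, gap_extend = -1)
  } else {
    list(matrix = .blosum62(), gap_open = -10, gap_extend = -1)
  }
}

.resolve_scoring <- function(scoring, type) {
  def <- default_scoring(type)
  if (is.null(scoring)) return(def)
  if (!is.null(scoring$matrix)) def$matrix <- scoring$matrix
  if (!is.null(scoring$match) || !is.null(scoring$mismatch)) {
    if (type != "dna") stop("match/mismatch scoring applies to type = 'dna'")
    match <- if (is.null(scoring$match)) 2 else scoring$match
    mismatch <- if (is.null(scoring$mismatch)) -1 else scoring$mismatch
    m <- matrix(mismatch, 4, 4, dimnames = list(BASES, BASES))
    diag(m) <- match
    def$matrix <- m
  }
  if (!is.null(scoring$gap_open)) def$gap_open <- scoring$gap_open
  if (!is.null(scoring$gap_extend)) def$gap_extend <- scoring$gap_extend
  def
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch with affine gap penalties (Gotoh). Traceback ties are
#' broken deterministically (diagonal, then gap in the second sequence, then
#' gap in the first), so the same inputs give the same alignment on every
#' platform.
#'
#' @param seq_a,seq_b Non-empty sequences (case-insensitive).
#' @param scoring Optional list overriding [default_scoring()]: `match`,
#'   `mismatch` (nucleotide shortcut), `matrix`, `gap_open`, `gap_extend`.
#' @param type `"dna"` or `"protein"`.
#' @param id_a,id_b Identifiers carried into the result.
#' @return Object of class `pairwise_alignment`: `id_a`, `id_b`, `aligned_a`,
#'   `aligned_b` (equal-length, gapped with `-`), `score`.
#' @export
global_align <- function(seq_a, seq_b, scoring = NULL,
                         type = c("dna", "protein"),
                         id_a = "a", id_b = "b") {
  type <- match.arg(type)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (type == "dna") {
    seq_a <- gsub("U", "T", seq_a, fixed = TRUE)
    seq_b <- gsub("U", "T", seq_b, fixed = TRUE)
  }
  sc <- .resolve_scoring(scoring, type)
  alphabet <- paste0(rownames(sc$matrix), collapse = "")
  res <- nw_align_cpp(seq_a, seq_b, sc$matrix, alphabet,
                      sc$gap_open, sc$gap_extend)
  structure(list(id_a = id_a, id_b = id_b,
                 aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise alignment (", nchar(x$aligned_a), " columns, score ",
      x$score, ")\n", sep = "")
  cat(x$id_a, ": ", x$aligned_a, "\n", sep = "")
  cat(x$id_b, ": ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Gap-excluded identity of a pairwise alignment
#'
#' Identity is 1 - M/N, where M is the number of mismatching positions and N
#' the number of alignment columns at which neither sequence has a gap.
#' Columns with a gap in either row contribute to neither M nor N, so
#' insertions and deletions cannot deflate the score.
#'
#' @param aln A `pairwise_alignment`, or a character vector of two equal-length
#'   aligned strings.
#' @return Fraction in `[0, 1]`. Errors if no gap-free column exists (the
#'   score is undefined, not zero).
#' @export
identity_gap_excluded <- function(aln) {
  if (inherits(aln, "pairwise_alignment")) {
    a <- aln$aligned_a; b <- aln$aligned_b
  } else if (is.character(aln) && length(aln) == 2L) {
    a <- aln[1L]; b <- aln[2L]
  } else stop("aln must be a pairwise_alignment or two aligned strings")
  if (nchar(a) != nchar(b)) stop("aligned rows differ in length")
  nm <- gapfree_mismatch_cpp(a, b)
  if (nm[1L] == 0L)
    stop("identity undefined: no column is gap-free in both sequences")
  1 - nm[2L] / nm[1L]
}

#' 3'UTR similarity (gap-excluded identity)
#'
#' Globally aligns two 3'UTR sequences and returns their gap-excluded
#' identity, so that indel-rich UTR evolution does not deflate the score.
#'
#' @inheritParams global_align
#' @return Fraction in `[0, 1]`.
#' @export
utr3_similarity <- function(utr_a, utr_b, scoring = NULL) {
  identity_gap_excluded(global_align(utr_a, utr_b, scoring, type = "dna"))
}

## ---- codon-aware multiple alignment ------------------------------------

# Star-merge pairwise protein alignments (each vs the reference) into an MSA.
# Returns a character matrix (rows = sequences incl. reference first).
.star_merge <- function(ref, others, scoring = NULL) {
  L <- nchar(ref)
  per_seq <- lapply(others, function(s) {
    pa <- global_align(ref, s, scoring, type = "protein")
    ra <- strsplit(pa$aligned_a, "")[[1L]]
    sa <- strsplit(pa$aligned_b, "")[[1L]]
    at_ref <- character(L)            # residue (or '-') opposite each ref residue
    inserts <- vector("list", L + 1L) # insertions in slot r = after ref residue r
    r <- 0L
    for (k in seq_along(ra)) {
      if (ra[k] != "-") {
        r <- r + 1L
        at_ref[r] <- sa[k]
      } else {
        inserts[[r + 1L]] <- c(inserts[[r + 1L]], sa[k])
      }
    }
    list(at_ref = at_ref, inserts = inserts)
  })
  slot_len <- vapply(seq_len(L + 1L), function(s)
    max(0L, vapply(per_seq, function(p) length(p$inserts[[s]]), integer(1))),
    integer(1))
  build_row <- function(at_ref, inserts) {
    out <- character(0)
    for (s in seq_len(L + 1L)) {
      ins <- inserts[[s]]
      out <- c(out, ins, rep("-", slot_len[s] - length(ins)))
      if (s <= L) out <- c(out, at_ref[s])
    }
    out
  }
  ref_row <- build_row(strsplit(ref, "")[[1L]],
                       rep(list(character(0)), L + 1L))
  rows <- lapply(per_seq, function(p) build_row(p$at_ref, p$inserts))
  do.call(rbind, c(list(ref_row), rows))
}

#' Codon-aware multiple alignment of coding sequences
#'
#' Aligns CDSs at the protein level and back-translates, so gaps occur only
#' in whole-codon triplets and every column keeps its codon-position meaning.
#' When all CDSs encode the identical protein (the motivating case for
#' duplicate genes with an invariant product) the alignment is gap-free
#' column stacking; otherwise a star progressive alignment around the longest
#' protein is used. A terminal stop codon, where present, is kept as a final
#' codon column (rows without one are gap-padded) so that ungapping a row
#' always recovers its input CDS.
#'
#' @param cds_set Named character vector (or named list) of at least two CDSs.
#' @param scoring Optional protein scoring override for the non-identical case.
#' @return Object of class `codon_alignment`: `ids`, `rows` (named, equal
#'   length, divisible by 3), `n_codon_columns`.
#' @export
codon_align <- function(cds_set, scoring = NULL) {
  cds_set <- unlist(cds_set)
  if (length(cds_set) < 2L) stop("need at least two CDSs to align")
  if (is.null(names(cds_set)) || anyNA(names(cds_set)) ||
      any(!nzchar(names(cds_set))))
    names(cds_set) <- paste0("seq", seq_along(cds_set))
  cds_set <- vapply(cds_set, .check_cds, character(1))
  prots <- vapply(cds_set, translate_cds, character(1))
  codons <- lapply(cds_set, split_codons)
  tab <- .genetic_code()
  has_stop <- vapply(codons, function(cd) tab[[cd[length(cd)]]] == "*",
                     logical(1))
  body <- lapply(seq_along(codons), function(i)
    if (has_stop[i]) codons[[i]][-length(codons[[i]])] else codons[[i]])

  if (length(unique(prots)) == 1L) {
    aligned <- do.call(rbind, body)   # identical proteins: column stacking
  } else {
    ref_i <- which.max(nchar(prots))
    msa <- .star_merge(prots[ref_i], prots[-ref_i], scoring)
    order_back <- c(ref_i, seq_along(prots)[-ref_i])
    aligned <- matrix("", nrow = length(prots), ncol = ncol(msa))
    for (k in seq_along(order_back)) {
      i <- order_back[k]
      cod <- body[[i]]
      row <- msa[k, ]
      out <- character(length(row))
      ci <- 0L
      for (j in seq_along(row)) {
        if (row[j] == "-") out[j] <- "---"
        else { ci <- ci + 1L; out[j] <- cod[ci] }
      }
      aligned[i, ] <- out
    }
  }
  if (any(has_stop)) {
    stop_col <- vapply(seq_along(codons), function(i)
      if (has_stop[i]) codons[[i]][length(codons[[i]])] else "---",
      character(1))
    aligned <- cbind(aligned, stop_col)
  }
  rows <- apply(aligned, 1L, paste0, collapse = "")
  names(rows) <- names(cds_set)
  structure(list(ids = names(cds_set), rows = rows,
                 n_codon_columns = ncol(aligned)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment: ", length(x$ids), " sequences, ",
      x$n_codon_columns, " codon columns\n", sep = "")
  invisible(x)
}

# codon-column matrix of a codon_alignment (rows x codon columns)
.codon_matrix <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  t(vapply(aln$rows, function(r) split_gapped_codons(r),
           character(aln$n_codon_columns)))
}

# split a gapped row into codon triplets without ACGT validation
split_gapped_codons <- function(row) {
  n <- nchar(row) %/% 3L
  substring(row, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

## ---- FASTA / PHYLIP I/O -------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; for nucleotide data, U is normalized to T.
#'
#' @param path FASTA file (wrapped or single-line records).
#' @param type `"dna"` or `"protein"` (controls U -> T normalization).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (type == "dna") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write an alignment in relaxed sequential PHYLIP format
#'
#' For handing a codon alignment to external phylogenetics tools.
#'
#' @param aln A `codon_alignment`, or a named character vector of equal-length
#'   aligned rows.
#' @param path Output path.
#' @export
write_phylip <- function(aln, path) {
  rows <- if (inherits(aln, "codon_alignment")) aln$rows else aln
  if (length(unique(nchar(rows))) != 1L) stop("rows differ in length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(rows), nchar(rows[1L])), con)
  writeLines(sprintf("%s  %s", names(rows), unname(rows)), con)
  invisible(path)
}
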