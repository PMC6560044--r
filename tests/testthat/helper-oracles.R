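# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: translation goes through seqinr, alignments are
# enumerated as explicit gapped string pairs, and rank-sum p-values come
# from full permutation enumeration.

# translate one codon with seqinr (independent of the package's code table)
oracle_translate_codon <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

# brute-force degeneracy: substitute all four bases and translate via seqinr
oracle_fold <- function(codon, position) {
  aa <- oracle_translate_codon(codon)
  sum(vapply(c("A", "C", "G", "T"), function(b) {
    v <- codon
    substr(v, position, position) <- b
    oracle_translate_codon(v) == aa
  }, logical(1)))
}

# enumerate every global alignment of a and b as pairs of gapped strings
# (no column gapped in both rows)
enum_alignments <- function(a, b) {
  if (!nzchar(a) && !nzchar(b)) return(list(c("", "")))
  res <- list()
  if (nzchar(a) && nzchar(b)) {
    for (r in enum_alignments(substring(a, 2), substring(b, 2)))
      res <- c(res, list(c(paste0(substr(a, 1, 1), r[1]),
                           paste0(substr(b, 1, 1), r[2]))))
  }
  if (nzchar(a)) {
    for (r in enum_alignments(substring(a, 2), b))
      res <- c(res, list(c(paste0(substr(a, 1, 1), r[1]),
                           paste0("-", r[2]))))
  }
  if (nzchar(b)) {
    for (r in enum_alignments(a, substring(b, 2)))
      res <- c(res, list(c(paste0("-", r[1]),
                           paste0(substr(b, 1, 1), r[2]))))
  }
  res
}

# score one gapped alignment under the affine model
# (gap of length k costs gap_open + k * gap_extend)
score_alignment <- function(ra, rb, match = 2, mismatch = -1,
                            gap_open = -5, gap_extend = -1) {
  ca <- strsplit(ra, "")[[1]]
  cb <- strsplit(rb, "")[[1]]
  s <- 0
  prev <- "none"
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      s <- s + gap_extend + (if (prev != "gap_a") gap_open else 0)
      prev <- "gap_a"
    } else if (cb[k] == "-") {
      s <- s + gap_extend + (if (prev != "gap_b") gap_open else 0)
      prev <- "gap_b"
    } else {
      s <- s + (if (ca[k] == cb[k]) match else mismatch)
      prev <- "aligned"
    }
  }
  s
}

# best score over all enumerated alignments
oracle_best_score <- function(a, b, ...) {
  max(vapply(enum_alignments(a, b), function(r)
    score_alignment(r[1], r[2], ...), numeric(1)))
}

# exact Mann-Whitney p-value by enumerating all C(n, n_a) group assignments
oracle_ranksum_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  n_a <- length(a)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - n_a * (n_a + 1) / 2
  u_obs <- u_of(seq_len(n_a))
  us <- apply(utils::combn(length(pooled), n_a), 2, u_of)
  pl <- mean(us <= u_obs)
  pg <- mean(us >= u_obs)
  switch(alternative,
         less = pl, greater = pg,
         two.sided = min(1, 2 * min(pl, pg)))
}

# hand-count gap-excluded identity by scanning columns in R
oracle_identity <- function(ra, rb) {
  ca <- strsplit(ra, "")[[1]]
  cb <- strsplit(rb, "")[[1]]
  keep <- ca != "-" & cb != "-"
  stopifnot(any(keep))
  1 - sum(ca[keep] != cb[keep]) / sum(keep)
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

# random CDS for a random protein (no stop), length n_codons
random_cds <- function(n_codons) {
  sc <- sense_codons()
  paste0(sample(sc, n_codons, replace = TRUE), collapse = "")
}

# random pair of aligned rows with gaps but no both-gap column and at least
# one gap-free column
random_gapped_pair <- function(len = 30, gap_p = 0.15) {
  repeat {
    ca <- character(0); cb <- character(0)
    for (k in seq_len(len)) {
      r <- stats::runif(1)
      if (r < gap_p) {
        ca <- c(ca, "-"); cb <- c(cb, sample(c("A", "C", "G", "T"), 1))
      } else if (r < 2 * gap_p) {
        ca <- c(ca, sample(c("A", "C", "G", "T"), 1)); cb <- c(cb, "-")
      } else {
        ca <- c(ca, sample(c("A", "C", "G", "T"), 1))
        cb <- c(cb, sample(c("A", "C", "G", "T"), 1))
      }
    }
    if (any(ca != "-" & cb != "-"))
      return(c(paste0(ca, collapse = ""), paste0(cb, collapse = "")))
  }
}
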