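## Codon usage: per-gene and pooled profiles under two metrics, Pearson
## correlation between profiles, benchmarking of a focal gene against
## transcriptional-program gene sets (proliferation vs differentiation) and a
## genome-wide reference, and Kazusa-style codon usage table I/O.
##
## Metrics. "raw_frequency": codon occurrences divided by the total codon
## count of the gene. "aa_specific": occurrences divided by the count of the
## encoded amino acid -- the probability that a codon is used given that its
## amino acid is used, which corrects for amino-acid composition bias.

#' Count sense codons in a CDS
#'
#' @param cds Translatable coding sequence; a terminal stop codon is dropped.
#' @return Named integer vector over all 61 sense codons (zeros included).
#' @export
codon_counts <- function(cds) {
  codons <- split_codons(cds)
  translate_cds(cds)  # validates: internal stops etc.
  tab <- .genetic_code()
  if (tab[[codons[length(codons)]]] == "*") codons <- codons[-length(codons)]
  sc <- sense_codons()
  counts <- stats::setNames(integer(length(sc)), sc)
  tb <- table(codons)
  counts[names(tb)] <- as.integer(tb)
  counts
}

.as_counts <- function(x) {
  if (inherits(x, "codon_usage_profile")) return(x$counts)
  sc <- sense_codons()
  if (is.null(names(x)) || !all(names(x) %in% c(sc, "TAA", "TAG", "TGA")))
    stop("counts must be named by codons")
  counts <- stats::setNames(integer(length(sc)), sc)
  x <- x[names(x) %in% sc]
  counts[names(x)] <- as.integer(round(x))
  counts
}

.new_profile <- function(metric, counts, frequencies, source) {
  structure(list(metric = metric, counts = counts,
                 frequencies = frequencies, source = source),
            class = "codon_usage_profile")
}

#' @export
print.codon_usage_profile <- function(x, ...) {
  cat(sprintf("codon usage profile [%s] from %s: %d codons counted\n",
              x$metric, x$source, sum(x$counts)))
  invisible(x)
}

#' Raw codon frequencies
#'
#' Each codon's occurrences divided by the total number of codons.
#'
#' @param counts Named codon counts (from [codon_counts()]) or a profile.
#' @param source Label for the profile origin.
#' @return `codon_usage_profile` with metric `"raw_frequency"`.
#' @export
raw_frequencies <- function(counts, source = "gene") {
  counts <- .as_counts(counts)
  total <- sum(counts)
  if (total == 0L) stop("empty counts: no sense codons")
  .new_profile("raw_frequency", counts, counts / total, source)
}

#' Amino-acid-specific codon frequencies
#'
#' Each codon's occurrences divided by the occurrences of its amino acid:
#' the conditional probability of the codon given the amino acid. Codons of
#' amino acids absent from the gene are undefined (NA), not zero.
#'
#' @inheritParams raw_frequencies
#' @return `codon_usage_profile` with metric `"aa_specific"`.
#' @export
aa_specific_frequencies <- function(counts, source = "gene") {
  counts <- .as_counts(counts)
  if (sum(counts) == 0L) stop("empty counts: no sense codons")
  tab <- .genetic_code()
  aa_of <- tab[names(counts)]
  aa_tot <- tapply(counts, aa_of, sum)
  freq <- counts / as.numeric(aa_tot[aa_of])
  freq[aa_tot[aa_of] == 0] <- NA_real_
  .new_profile("aa_specific", counts, freq, source)
}

#' Pooled codon usage profile of a gene set
#'
#' Counts are pooled across genes and the metric normalization applied to
#' the pool (robust to gene-length variation, unlike a mean of per-gene
#' profiles).
#'
#' @param genes List of codon-count vectors (or profiles), length >= 1.
#' @param metric `"aa_specific"` or `"raw_frequency"`.
#' @param source Label for the pooled profile.
#' @param method `"pooled"` (default) pools counts before normalizing;
#'   `"mean"` averages per-gene frequency vectors instead (undefined
#'   dimensions dropped gene-wise).
#' @return `codon_usage_profile`.
#' @export
group_profile <- function(genes, metric = c("aa_specific", "raw_frequency"),
                          source = "gene-set",
                          method = c("pooled", "mean")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (length(genes) == 0L) stop("empty gene set")
  mk <- function(counts) {
    if (metric == "aa_specific") aa_specific_frequencies(counts, source)
    else raw_frequencies(counts, source)
  }
  pooled <- Reduce(`+`, lapply(genes, .as_counts))
  if (method == "pooled") return(mk(pooled))
  freqs <- do.call(rbind, lapply(genes, function(g) mk(.as_counts(g))$frequencies))
  prof <- mk(pooled)
  prof$frequencies <- colMeans(freqs, na.rm = TRUE)
  prof$frequencies[is.nan(prof$frequencies)] <- NA_real_
  prof
}

#' Pearson correlation between two codon usage profiles
#'
#' Correlates the two frequency vectors over shared, defined codon
#' dimensions. Under the amino-acid-specific metric the single-codon amino
#' acids (Met/ATG, Trp/TGG) are excluded by default: their frequency is
#' constant 1 and would inflate r. Undefined dimensions (absent amino acids)
#' are dropped pairwise, never imputed as zero.
#'
#' @param p_a,p_b Profiles sharing the same metric.
#' @param codon_filter Optional character vector of codons to use; default:
#'   all sense codons, minus ATG and TGG under `aa_specific`.
#' @return Object of class `correlation_result`: `r`, `n_codons`,
#'   `profile_a`, `profile_b`.
#' @export
profile_correlation <- function(p_a, p_b, codon_filter = NULL) {
  stopifnot(inherits(p_a, "codon_usage_profile"),
            inherits(p_b, "codon_usage_profile"))
  if (p_a$metric != p_b$metric)
    stop("profiles use different metrics: ", p_a$metric, " vs ", p_b$metric)
  if (is.null(codon_filter)) {
    codon_filter <- sense_codons()
    if (p_a$metric == "aa_specific")
      codon_filter <- setdiff(codon_filter, c("ATG", "TGG"))
  }
  fa <- p_a$frequencies[codon_filter]
  fb <- p_b$frequencies[codon_filter]
  keep <- !is.na(fa) & !is.na(fb)
  if (sum(keep) < 3L)
    stop("fewer than 3 shared defined codon dimensions")
  fa <- fa[keep]; fb <- fb[keep]
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0)
    stop("zero variance in a profile over the retained codons")
  structure(list(r = stats::cor(fa, fb), n_codons = sum(keep),
                 profile_a = p_a$source, profile_b = p_b$source),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%s, %s) = %.4f over %d codons\n",
              x$profile_a, x$profile_b, x$r, x$n_codons))
  invisible(x)
}

#' Benchmark a gene's codon usage against transcriptional-program profiles
#'
#' Correlates a focal gene's codon usage with the pooled proliferation,
#' differentiation and genome-wide profiles, and places it within the
#' benchmark distributions formed by correlating every program gene with its
#' own and the opposite group profile. When the focal gene is itself a member
#' of a program set it is left out of that group's pooled profile
#' (leave-one-out) to avoid self-correlation bias; switch off with
#' `leave_one_out = FALSE` for literal pooling.
#'
#' @param gene_counts Codon counts of the focal gene.
#' @param proliferation,differentiation Named lists of codon-count vectors
#'   for the two program gene sets.
#' @param genomewide Optional genome-wide `codon_usage_profile` (same metric).
#' @param metric `"aa_specific"` or `"raw_frequency"`.
#' @param gene_id Focal gene id (used for leave-one-out membership).
#' @param leave_one_out Drop the focal gene from its own group profile.
#' @param codon_filter Passed to [profile_correlation()].
#' @return Object of class `program_benchmark`: per-profile correlations,
#'   benchmark distributions, `assignment` (`"proliferation"`,
#'   `"differentiation"` or `"ambiguous"`), and own/opposite-group
#'   percentiles of the focal gene.
#' @export
benchmark_gene <- function(gene_counts, proliferation, differentiation,
                           genomewide = NULL,
                           metric = c("aa_specific", "raw_frequency"),
                           gene_id = "focal", leave_one_out = TRUE,
                           codon_filter = NULL) {
  metric <- match.arg(metric)
  mk <- function(counts, src) {
    if (metric == "aa_specific") aa_specific_frequencies(counts, src)
    else raw_frequencies(counts, src)
  }
  drop_focal <- function(set) {
    if (leave_one_out && gene_id %in% names(set))
      set[names(set) != gene_id] else set
  }
  prol_set <- drop_focal(proliferation)
  diff_set <- drop_focal(differentiation)
  prol_prof <- group_profile(prol_set, metric, "proliferation")
  diff_prof <- group_profile(diff_set, metric, "differentiation")
  focal_prof <- mk(.as_counts(gene_counts), gene_id)

  r_prol <- profile_correlation(focal_prof, prol_prof, codon_filter)$r
  r_diff <- profile_correlation(focal_prof, diff_prof, codon_filter)$r
  r_gw <- if (!is.null(genomewide))
    profile_correlation(focal_prof, genomewide, codon_filter)$r else NA_real_

  bench <- function(set, own_prof, other_prof) {
    pool <- Reduce(`+`, lapply(set, .as_counts))
    own <- vapply(names(set), function(id) {
      cnt <- .as_counts(set[[id]])
      prof <- if (leave_one_out) mk(pool - cnt, "loo") else own_prof
      profile_correlation(mk(cnt, id), prof, codon_filter)$r
    }, numeric(1))
    opp <- vapply(names(set), function(id)
      profile_correlation(mk(.as_counts(set[[id]]), id), other_prof,
                          codon_filter)$r, numeric(1))
    list(own = own, opposite = opp)
  }
  prol_bench <- bench(prol_set, prol_prof, diff_prof)
  diff_bench <- bench(diff_set, diff_prof, prol_prof)

  assignment <- if (isTRUE(all.equal(r_prol, r_diff))) "ambiguous"
  else if (r_prol > r_diff) "proliferation" else "differentiation"
  pct <- function(r, dist) mean(dist <= r)

  structure(list(gene_id = gene_id,
                 r_vs_proliferation = r_prol,
                 r_vs_differentiation = r_diff,
                 r_vs_genomewide = r_gw,
                 proliferation_benchmark = prol_bench,
                 differentiation_benchmark = diff_bench,
                 percentile_in_proliferation = pct(r_prol, prol_bench$own),
                 percentile_in_differentiation = pct(r_diff, diff_bench$own),
                 assignment = assignment, metric = metric),
            class = "program_benchmark")
}

#' @export
print.program_benchmark <- function(x, ...) {
  cat(sprintf(
    "%s [%s]: r_prolif = %.3f, r_diff = %.3f, r_genomewide = %s -> %s\n",
    x$gene_id, x$metric, x$r_vs_proliferation, x$r_vs_differentiation,
    ifelse(is.na(x$r_vs_genomewide), "NA", sprintf("%.3f", x$r_vs_genomewide)),
    x$assignment))
  invisible(x)
}

#' Assign a gene to the transcriptional program it correlates best with
#'
#' Lightweight companion to [benchmark_gene()]: correlates the gene with the
#' two pooled program profiles (leave-one-out when the gene belongs to a set)
#' and returns the argmax, without computing the full benchmark
#' distributions.
#'
#' @inheritParams benchmark_gene
#' @return List with `assignment`, `r_vs_proliferation`,
#'   `r_vs_differentiation`.
#' @export
assign_program <- function(gene_counts, proliferation, differentiation,
                           metric = c("aa_specific", "raw_frequency"),
                           gene_id = "focal", leave_one_out = TRUE,
                           codon_filter = NULL) {
  metric <- match.arg(metric)
  mk <- function(counts, src) {
    if (metric == "aa_specific") aa_specific_frequencies(counts, src)
    else raw_frequencies(counts, src)
  }
  cnt <- .as_counts(gene_counts)
  pool_of <- function(set) {
    pool <- Reduce(`+`, lapply(set, .as_counts))
    if (leave_one_out && gene_id %in% names(set)) pool - cnt else pool
  }
  r_prol <- profile_correlation(mk(cnt, gene_id),
                                mk(pool_of(proliferation), "proliferation"),
                                codon_filter)$r
  r_diff <- profile_correlation(mk(cnt, gene_id),
                                mk(pool_of(differentiation), "differentiation"),
                                codon_filter)$r
  assignment <- if (isTRUE(all.equal(r_prol, r_diff))) "ambiguous"
  else if (r_prol > r_diff) "proliferation" else "differentiation"
  list(assignment = assignment, r_vs_proliferation = r_prol,
       r_vs_differentiation = r_diff)
}

## ---- Kazusa-style codon usage tables -----------------------------------

#' Read a Kazusa-style codon usage table
#'
#' Parses the whitespace-separated layout used by the Kazusa codon usage
#' database: repeating triplets of codon, per-mille frequency and raw count,
#' in either RNA (UUU) or DNA (TTT) spelling. All 64 codons must be present.
#'
#' @param path Table file.
#' @param source Label for the resulting profile.
#' @return `codon_usage_profile` (raw counts retained; metric
#'   `"raw_frequency"`, re-normalizable with [aa_specific_frequencies()]).
#' @export
read_codon_table <- function(path, source = "genome-wide") {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tokens <- unlist(strsplit(paste(txt, collapse = " "), "[[:space:]()]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) %% 3L != 0L)
    stop("malformed codon table: token count not a multiple of 3")
  codons <- toupper(gsub("U", "T", tokens[seq(1, length(tokens), 3L)]))
  counts <- suppressWarnings(as.numeric(tokens[seq(3, length(tokens), 3L)]))
  if (any(!grepl("^[ACGT]{3}$", codons)) || anyNA(counts))
    stop("malformed codon table rows")
  all64 <- names(.genetic_code())
  missing <- setdiff(all64, codons)
  if (length(missing) > 0L)
    stop("codon table is missing codons: ", paste(missing, collapse = ", "))
  counts <- stats::setNames(counts, codons)[sense_codons()]
  raw_frequencies(round(counts), source)
}

#' Write codon counts as a Kazusa-style table
#'
#' Round-trips bit-exactly through [read_codon_table()]. Stop codons are
#' written with zero counts unless supplied.
#'
#' @param counts Named codon counts (sense codons; stop codons optional) or a
#'   profile.
#' @param path Output path.
#' @export
write_codon_table <- function(counts, path) {
  counts <- if (inherits(counts, "codon_usage_profile")) counts$counts
            else counts
  all64 <- names(.genetic_code())
  full <- stats::setNames(numeric(64), all64)
  full[names(counts)] <- counts
  per_mille <- if (sum(full) > 0) 1000 * full / sum(full) else full
  entries <- sprintf("%s %.1f %d", gsub("T", "U", all64),
                     per_mille, as.integer(full))
  lines <- vapply(split(entries, ceiling(seq_along(entries) / 4)),
                  paste, character(1), collapse = "  ")
  writeLines(lines, path)
  invisible(path)
}

#' Jensen-Shannon divergence between two codon usage profiles
#'
#' Computed on the per-codon probability distributions implied by the raw
#' counts (base-2 logarithm, so the value lies in `[0, 1]`). Used to state
#' how separated two generating profiles are.
#'
#' @param p_a,p_b `codon_usage_profile` objects or count vectors.
#' @return Divergence in `[0, 1]`.
#' @export
js_divergence <- function(p_a, p_b) {
  a <- .as_counts(p_a); b <- .as_counts(p_b)
  p <- a / sum(a); q <- b / sum(b)
  m <- (p + q) / 2
  kl <- function(x, y) {
    keep <- x > 0
    sum(x[keep] * log2(x[keep] / y[keep]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Read a gene-set list file
#'
#' One gene id per line; `#` starts a comment.
#'
#' @param path List file.
#' @return Character vector of ids.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write a gene-set list file
#' @param ids Character vector of gene ids.
#' @param path Output path.
#' @export
write_gene_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}
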