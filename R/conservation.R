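## Nucleotide-level selection analysis: raw substitution scores (observed
## substitutions / CDS length), site classification (wobble and fourfold
## degenerate third positions), absolutely conserved site frequencies and
## their between-paralog ratio, GC3, and the Mann-Whitney rank-sum test used
## to compare score distributions.

#' Pairwise nucleotide substitution score
#'
#' The observed number of nucleotide substitutions divided by the CDS length:
#' a raw (uncorrected) genetic distance. Sequences are codon-aligned first;
#' the denominator is the number of gap-free alignment columns, which equals
#' the CDS length in the equal-length identical-protein case this analysis
#' targets.
#'
#' @param cds_a,cds_b Translatable coding sequences.
#' @param denominator What to divide the mismatch count by: gap-free
#'   alignment columns (the default, equal to the CDS length when the two
#'   CDSs have equal length), or the shorter/mean CDS length.
#' @return Fraction in `[0, 1]`.
#' @examples
#' substitution_score("ATGGCT", "ATGGCC")  # 1/6
#' @export
substitution_score <- function(cds_a, cds_b,
                               denominator = c("gapfree_columns",
                                               "min_length", "mean_length")) {
  denominator <- match.arg(denominator)
  aln <- codon_align(c(a = cds_a, b = cds_b))
  nm <- gapfree_mismatch_cpp(aln$rows[[1L]], aln$rows[[2L]])
  if (nm[1L] == 0L) stop("no gap-free columns between the two CDSs")
  denom <- switch(denominator,
                  gapfree_columns = nm[1L],
                  min_length = min(nchar(cds_a), nchar(cds_b)),
                  mean_length = mean(c(nchar(cds_a), nchar(cds_b))))
  nm[2L] / denom
}

#' All-pairs substitution-score matrix
#'
#' @param genes Named character vector (or list) of CDSs, length >= 2.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = gene ids.
#' @export
distance_matrix <- function(genes) {
  genes <- unlist(genes)
  if (length(genes) < 2L) stop("need at least two genes")
  if (is.null(names(genes))) names(genes) <- paste0("g", seq_along(genes))
  n <- length(genes)
  d <- matrix(0, n, n, dimnames = list(names(genes), names(genes)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- substitution_score(genes[[i]], genes[[j]])
    }
  }
  d
}

#' Lower-triangle pairwise scores as a long table
#'
#' @param d Matrix from [distance_matrix()].
#' @param group Optional group label column.
#' @return data.frame with `id_a`, `id_b`, `group`, `score`.
#' @export
distance_long <- function(d, group = NA_character_) {
  idx <- which(lower.tri(d), arr.ind = TRUE)
  data.frame(id_a = rownames(d)[idx[, "row"]],
             id_b = colnames(d)[idx[, "col"]],
             group = group,
             score = d[idx],
             stringsAsFactors = FALSE)
}

#' Classify codon-alignment columns by degeneracy
#'
#' Labels each gap-free codon column of the alignment: a third-position site
#' is a wobble site when synonymous substitutions are possible in every row
#' (fold >= 2), and a fourfold degenerate site when in every row any
#' nucleotide substitution at that position is synonymous (fold == 4).
#' Codon columns containing a gap or a stop codon in any row are excluded.
#'
#' @param aln A `codon_alignment`.
#' @return data.frame with one row per codon column: `codon_column`,
#'   `included`, `is_wobble`, `is_fourfold`.
#' @export
classify_sites <- function(aln) {
  m <- .codon_matrix(aln)
  fold3 <- .fold3_table()
  tab <- .genetic_code()
  res <- data.frame(codon_column = seq_len(ncol(m)),
                    included = FALSE, is_wobble = FALSE, is_fourfold = FALSE)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "---")) next
    if (any(tab[col] == "*")) next          # stop codons are not classified
    folds <- fold3[col]
    res$included[j] <- TRUE
    res$is_wobble[j] <- all(folds >= 2L)
    res$is_fourfold[j] <- all(folds == 4L)
  }
  res
}

#' Absolutely conserved site report
#'
#' Counts alignment columns of a site class (all third positions, wobble
#' positions, or fourfold degenerate sites) at which the nucleotide is
#' identical in every row, i.e. conserved across all organisms of the group.
#'
#' @param aln A `codon_alignment` with >= 2 rows.
#' @param site_class `"third_position"`, `"wobble"` or `"fourfold"`.
#' @param group_name Label carried into the report.
#' @return Object of class `conservation_report`: `group_name`, `site_class`,
#'   `conserved_count`, `total_sites`, `frequency` (NA when `total_sites`
#'   is 0, flagged by `undefined = TRUE`).
#' @export
conserved_report <- function(aln,
                             site_class = c("third_position", "wobble",
                                            "fourfold"),
                             group_name = "group") {
  site_class <- match.arg(site_class)
  if (length(aln$ids) < 2L) stop("need an alignment of at least two rows")
  cls <- classify_sites(aln)
  keep <- switch(site_class,
                 third_position = cls$included,
                 wobble = cls$is_wobble,
                 fourfold = cls$is_fourfold)
  cols <- cls$codon_column[keep]
  m <- .codon_matrix(aln)
  conserved <- vapply(cols, function(j) {
    thirds <- substr(m[, j], 3L, 3L)
    length(unique(thirds)) == 1L
  }, logical(1))
  total <- length(cols)
  structure(list(group_name = group_name, site_class = site_class,
                 conserved_count = sum(conserved), total_sites = total,
                 frequency = if (total > 0L) sum(conserved) / total else NA_real_,
                 undefined = total == 0L),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("conservation report [%s, %s]: %d / %d conserved (freq %s)\n",
              x$group_name, x$site_class, x$conserved_count, x$total_sites,
              if (x$undefined) "undefined" else format(x$frequency)))
  invisible(x)
}

#' Ratio of conserved-site frequencies between two reports
#'
#' The over-representation of absolutely conserved sites in one gene relative
#' to the other (e.g. the slow paralog over the fast one). Values above 1
#' indicate stronger synonymous-site conservation in the first gene.
#'
#' @param report_a,report_b `conservation_report` objects with defined
#'   frequencies; `report_b` must have frequency > 0.
#' @return Numeric ratio `frequency_a / frequency_b`.
#' @export
freq_ratio <- function(report_a, report_b) {
  for (r in list(report_a, report_b))
    if (!inherits(r, "conservation_report") || r$undefined)
      stop("both arguments must be conservation reports with defined frequencies")
  if (report_b$frequency == 0)
    stop("frequency ratio undefined: denominator frequency is zero")
  report_a$frequency / report_b$frequency
}

#' GC content at third codon positions (GC3)
#'
#' @param cds Translatable coding sequence; a terminal stop codon is excluded.
#' @return Fraction of third positions carrying G or C.
#' @export
gc3 <- function(cds) {
  codons <- split_codons(cds)
  tab <- .genetic_code()
  if (tab[[codons[length(codons)]]] == "*") codons <- codons[-length(codons)]
  if (length(codons) == 0L) stop("no sense codons in CDS")
  translate_cds(cds)  # validates (internal stop etc.)
  thirds <- substr(codons, 3L, 3L)
  mean(thirds %in% c("G", "C"))
}

#' Mann-Whitney rank-sum comparison of two score distributions
#'
#' Wraps the Wilcoxon rank-sum machinery: exact distribution when the smaller
#' group has at most 8 values and there are no ties; otherwise the normal
#' approximation with tie and continuity correction. Degenerate input (all
#' values identical across both groups) yields p = 1 with a warning.
#'
#' @param values_a,values_b Nonempty numeric vectors.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return Object of class `rank_sum_result`: `u_statistic`, `p_value`,
#'   `n_a`, `n_b`, `exact`.
#' @export
rank_sum_test <- function(values_a, values_b,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be nonempty")
  n_a <- length(values_a); n_b <- length(values_b)
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(structure(list(u_statistic = n_a * n_b / 2, p_value = 1,
                          n_a = n_a, n_b = n_b, exact = FALSE),
                     class = "rank_sum_result"))
  }
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- !ties && min(n_a, n_b) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = alternative,
                                            exact = use_exact,
                                            correct = TRUE))
  structure(list(u_statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_a = n_a, n_b = n_b, exact = use_exact),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, %d), p = %g%s\n",
              x$u_statistic, x$n_a, x$n_b, x$p_value,
              if (x$exact) " [exact]" else ""))
  invisible(x)
}

#' Conservation report table (one row per report)
#'
#' @param reports List of `conservation_report` objects.
#' @return data.frame mirroring the per-group conserved/total/frequency
#'   summary, ready for TSV export.
#' @export
conservation_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(group = r$group_name, site_class = r$site_class,
               conserved = r$conserved_count, total = r$total_sites,
               frequency = r$frequency, stringsAsFactors = FALSE)))
}
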