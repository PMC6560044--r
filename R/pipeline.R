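## End-to-end orchestration: run every analysis stage from one configuration
## and write the figure-level tables (pairwise distances, conservation
## reports with between-paralog ratios, GC3, codon-usage correlations and
## program benchmarks, synteny matches, 3'UTR identity) as TSVs with
## '#'-prefixed metadata headers, plus a JSON run manifest. Each numeric
## cell is reproducible by calling the underlying function with the
## manifest's parameters.

#' Write a TSV with '#'-prefixed metadata header lines
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param meta Named list echoed as `# key: value` lines.
#' @export
write_tsv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects inputs, toggles and thresholds for [run_pipeline()]. Any stage
#' whose inputs are NULL (or whose toggle is FALSE) is skipped.
#'
#' @param out_dir Output directory.
#' @param families Named list of CDS FASTA paths, one ortholog panel per
#'   paralog (first two names define the numerator/denominator of the
#'   conservation frequency ratio).
#' @param species_groups Named list of sequence-id vectors defining nested
#'   organism groups (e.g. shallow to deep divergence).
#' @param codon_table Kazusa-style genome-wide codon usage table path.
#' @param gene_sets Named list with CDS FASTA paths `proliferation` and
#'   `differentiation` (optional `ueg`).
#' @param genome_a,genome_b Lists `list(bed=, fasta=, focal=)` for the
#'   synteny stage.
#' @param utr_fasta FASTA of 3'UTR sequences for the all-vs-all identity
#'   matrix.
#' @param metric Codon-usage metric.
#' @param synteny_thresholds See [default_synteny_thresholds()].
#' @param n_genes,window_bp Neighborhood caps.
#' @param do_conservation,do_codon_usage,do_synteny,do_utr Stage toggles.
#' @param seed Seed echoed into the manifest (stages are deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            families = NULL, species_groups = NULL,
                            codon_table = NULL, gene_sets = NULL,
                            genome_a = NULL, genome_b = NULL,
                            utr_fasta = NULL,
                            metric = c("aa_specific", "raw_frequency"),
                            synteny_thresholds = default_synteny_thresholds(),
                            n_genes = 30L, window_bp = 1.5e6,
                            do_conservation = TRUE, do_codon_usage = TRUE,
                            do_synteny = TRUE, do_utr = TRUE,
                            seed = 1L) {
  metric <- match.arg(metric)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage_conservation <- function(cfg, outputs) {
  fams <- lapply(cfg$families, read_fasta)
  meta <- list(stage = "conservation", seed = cfg$seed)
  # pairwise substitution scores per paralog
  long <- do.call(rbind, lapply(names(fams), function(p)
    distance_long(distance_matrix(fams[[p]]), group = p)))
  outputs$distances <- write_tsv_meta(long, file.path(cfg$out_dir,
                                                      "distances.tsv"), meta)
  # Mann-Whitney comparison of the first two paralogs' score distributions
  if (length(fams) >= 2L) {
    a <- long$score[long$group == names(fams)[1L]]
    b <- long$score[long$group == names(fams)[2L]]
    rs <- rank_sum_test(a, b)
    outputs$rank_sum <- write_tsv_meta(
      data.frame(group_a = names(fams)[1L], group_b = names(fams)[2L],
                 u = rs$u_statistic, p_value = rs$p_value,
                 n_a = rs$n_a, n_b = rs$n_b),
      file.path(cfg$out_dir, "rank_sum.tsv"), meta)
  }
  # conservation reports per species group and paralog, with ratios
  groups <- cfg$species_groups
  if (is.null(groups))
    groups <- list(all = names(fams[[1L]]))
  rows <- list(); ratios <- list()
  for (g in names(groups)) {
    reps <- list()
    for (p in names(fams)) {
      sub <- fams[[p]][intersect(names(fams[[p]]), groups[[g]])]
      if (length(sub) < 2L) next
      aln <- codon_align(sub)
      for (cls in c("third_position", "fourfold"))
        reps[[paste(p, cls)]] <- conserved_report(aln, cls,
                                                  paste(g, p, sep = ":"))
    }
    rows[[g]] <- conservation_table(reps)
    p12 <- names(fams)[1:2]
    for (cls in c("third_position", "fourfold")) {
      ra <- reps[[paste(p12[1L], cls)]]; rb <- reps[[paste(p12[2L], cls)]]
      if (!is.null(ra) && !is.null(rb) && !rb$undefined &&
          rb$frequency > 0)
        ratios[[paste(g, cls)]] <- data.frame(group = g, site_class = cls,
                                              ratio = freq_ratio(ra, rb))
    }
  }
  outputs$conservation <- write_tsv_meta(do.call(rbind, rows),
                                         file.path(cfg$out_dir,
                                                   "conservation.tsv"), meta)
  if (length(ratios) > 0L)
    outputs$freq_ratios <- write_tsv_meta(do.call(rbind, ratios),
                                          file.path(cfg$out_dir,
                                                    "freq_ratios.tsv"), meta)
  # GC3 per sequence
  gc3_tab <- do.call(rbind, lapply(names(fams), function(p)
    data.frame(paralog = p, id = names(fams[[p]]),
               gc3 = vapply(fams[[p]], gc3, numeric(1)))))
  outputs$gc3 <- write_tsv_meta(gc3_tab, file.path(cfg$out_dir, "gc3.tsv"),
                                meta)
  outputs
}

.stage_codon_usage <- function(cfg, outputs) {
  meta <- list(stage = "codon_usage", metric = cfg$metric, seed = cfg$seed)
  mk <- function(counts, src) {
    if (cfg$metric == "aa_specific") aa_specific_frequencies(counts, src)
    else raw_frequencies(counts, src)
  }
  gw <- if (!is.null(cfg$codon_table)) {
    prof <- read_codon_table(cfg$codon_table)
    mk(prof$counts, "genome-wide")
  } else NULL
  fams <- lapply(cfg$families, read_fasta)
  # per-gene correlation with the genome-wide profile
  if (!is.null(gw)) {
    cor_tab <- do.call(rbind, lapply(names(fams), function(p)
      do.call(rbind, lapply(names(fams[[p]]), function(id) {
        cr <- profile_correlation(mk(codon_counts(fams[[p]][[id]]), id), gw)
        data.frame(paralog = p, gene = id, reference = "genome-wide",
                   metric = cfg$metric, r = cr$r, n_codons = cr$n_codons)
      }))))
    outputs$genomewide_correlation <-
      write_tsv_meta(cor_tab, file.path(cfg$out_dir,
                                        "genomewide_correlation.tsv"), meta)
  }
  # program benchmarking of one representative gene per paralog
  if (!is.null(cfg$gene_sets)) {
    prol <- lapply(read_fasta(cfg$gene_sets$proliferation), codon_counts)
    diff <- lapply(read_fasta(cfg$gene_sets$differentiation), codon_counts)
    bench_tab <- do.call(rbind, lapply(names(fams), function(p) {
      rep_id <- names(fams[[p]])[1L]
      b <- benchmark_gene(codon_counts(fams[[p]][[rep_id]]), prol, diff,
                          genomewide = gw, metric = cfg$metric,
                          gene_id = paste(p, rep_id, sep = ":"))
      data.frame(paralog = p, gene = rep_id,
                 r_proliferation = b$r_vs_proliferation,
                 r_differentiation = b$r_vs_differentiation,
                 r_genomewide = b$r_vs_genomewide,
                 assignment = b$assignment)
    }))
    outputs$program_benchmark <-
      write_tsv_meta(bench_tab, file.path(cfg$out_dir,
                                          "program_benchmark.tsv"), meta)
  }
  outputs
}

.stage_synteny <- function(cfg, outputs) {
  meta <- c(list(stage = "synteny", n_genes = cfg$n_genes,
                 window_bp = cfg$window_bp, seed = cfg$seed),
            cfg$synteny_thresholds)
  ga <- read_gene_table(cfg$genome_a$bed, cfg$genome_a$fasta, "genome_a")
  gb <- read_gene_table(cfg$genome_b$bed, cfg$genome_b$fasta, "genome_b")
  na <- neighborhood(ga, cfg$genome_a$focal, cfg$n_genes, cfg$window_bp)
  nb <- neighborhood(gb, cfg$genome_b$focal, cfg$n_genes, cfg$window_bp)
  matches <- score_neighborhoods(na, nb, cfg$synteny_thresholds)
  outputs$synteny <- write_tsv_meta(matches,
                                    file.path(cfg$out_dir, "synteny.tsv"),
                                    meta)
  outputs
}

.stage_utr <- function(cfg, outputs) {
  meta <- list(stage = "utr", seed = cfg$seed)
  utrs <- read_fasta(cfg$utr_fasta)
  n <- length(utrs)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    rows[[length(rows) + 1L]] <-
      data.frame(id_a = names(utrs)[i], id_b = names(utrs)[j],
                 identity = utr3_similarity(utrs[[i]], utrs[[j]]))
  }
  outputs$utr_identity <- write_tsv_meta(do.call(rbind, rows),
                                         file.path(cfg$out_dir,
                                                   "utr_identity.tsv"), meta)
  outputs
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages against the configured inputs, writes their
#' tables under the output directory, and finishes with a JSON manifest
#' recording package version, seed, thresholds and produced files. A stage
#' failure aborts with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  run_stage <- function(name, enabled, has_inputs, fn) {
    if (!enabled || !has_inputs) return(invisible(NULL))
    tryCatch(outputs <<- fn(config, outputs),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  run_stage("conservation", config$do_conservation,
            !is.null(config$families), .stage_conservation)
  run_stage("codon_usage", config$do_codon_usage,
            !is.null(config$families), .stage_codon_usage)
  run_stage("synteny", config$do_synteny,
            !is.null(config$genome_a) && !is.null(config$genome_b),
            .stage_synteny)
  run_stage("utr", config$do_utr, !is.null(config$utr_fasta), .stage_utr)
  manifest <- list(
    package = "dupcodon",
    version = as.character(utils::packageVersion("dupcodon")),
    seed = config$seed, metric = config$metric,
    synteny_thresholds = config$synteny_thresholds,
    n_genes = config$n_genes, window_bp = config$window_bp,
    stages = list(conservation = config$do_conservation,
                  codon_usage = config$do_codon_usage,
                  synteny = config$do_synteny, utr = config$do_utr),
    outputs = lapply(outputs, basename))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outputs)
}
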