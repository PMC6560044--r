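## Quantitative synteny scan: extract the gene neighborhood around a focal
## locus (up to n genes per side and within a bp window), score every query
## flanking gene against a reference neighborhood by maximal CDS and protein
## gap-excluded identity, call syntenic genes under explicit thresholds, and
## pool reference neighborhoods across species for sensitivity.

.required_gene_cols <- c("gene_id", "chrom", "start", "end", "strand", "cds")

.check_gene_table <- function(genes) {
  if (!is.data.frame(genes)) stop("gene table must be a data.frame")
  miss <- setdiff(.required_gene_cols, names(genes))
  if (length(miss) > 0L)
    stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in table")
  genes
}

#' Default synteny-call thresholds
#'
#' A flanking gene is called syntenic when its best protein identity reaches
#' `protein` with at least `coverage` of the shorter protein in gap-free
#' columns, and its best CDS identity reaches `cds`. The values separate the
#' simulated ortholog and random-decoy regimes cleanly and are echoed into
#' all outputs.
#'
#' @return List with `protein`, `cds`, `coverage`.
#' @export
default_synteny_thresholds <- function() {
  list(protein = 0.40, cds = 0.50, coverage = 0.50)
}

#' Extract the gene neighborhood around a focal gene
#'
#' Takes up to `n_genes` genes on each side of the focal gene that lie within
#' `window_bp` of the focal gene's span (both caps apply simultaneously),
#' on the focal chromosome, in genomic order. Strand only labels sides
#' (upstream/downstream are relative to the focal gene's orientation); it
#' does not affect membership.
#'
#' @param annotations Gene table (data.frame with `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `cds`; 1-based inclusive coordinates).
#' @param focal_id Id of the focal gene.
#' @param n_genes Maximum flanking genes per side.
#' @param window_bp Maximum distance (bp) from the focal gene span.
#' @return Object of class `synteny_neighborhood`: `focal` (one-row
#'   data.frame), `flanking` (data.frame in genomic order with a `side`
#'   column), `n_genes`, `window_bp`.
#' @export
neighborhood <- function(annotations, focal_id, n_genes = 30L,
                         window_bp = 1.5e6) {
  annotations <- .check_gene_table(annotations)
  fi <- which(annotations$gene_id == focal_id)
  if (length(fi) != 1L) stop("focal gene not found: ", focal_id)
  focal <- annotations[fi, , drop = FALSE]
  same <- annotations[-fi, , drop = FALSE]
  same <- same[same$chrom == focal$chrom, , drop = FALSE]
  same <- same[same$end >= focal$start - window_bp &
               same$start <= focal$end + window_bp, , drop = FALSE]
  same <- same[order(same$start, same$gene_id), , drop = FALSE]
  left <- same[same$start < focal$start, , drop = FALSE]
  right <- same[same$start >= focal$start, , drop = FALSE]
  if (nrow(left) > n_genes)
    left <- left[seq(nrow(left) - n_genes + 1L, nrow(left)), , drop = FALSE]
  if (nrow(right) > n_genes)
    right <- right[seq_len(n_genes), , drop = FALSE]
  # upstream/downstream relative to the focal gene's transcription direction
  if (identical(focal$strand, "-")) {
    left$side <- rep("downstream", nrow(left))
    right$side <- rep("upstream", nrow(right))
  } else {
    left$side <- rep("upstream", nrow(left))
    right$side <- rep("downstream", nrow(right))
  }
  flanking <- rbind(left, right)
  if (nrow(flanking) == 0L)
    warning("focal gene has no neighbors on its chromosome/window")
  structure(list(focal = focal, flanking = flanking,
                 n_genes = n_genes, window_bp = window_bp),
            class = "synteny_neighborhood")
}

#' @export
print.synteny_neighborhood <- function(x, ...) {
  cat(sprintf("neighborhood of %s: %d flanking genes (caps: %d per side, %g bp)\n",
              x$focal$gene_id, nrow(x$flanking), x$n_genes, x$window_bp))
  invisible(x)
}

.flanking_of <- function(x) {
  if (inherits(x, "synteny_neighborhood")) x$flanking
  else .check_gene_table(x)
}

#' Score a query neighborhood against a reference
#'
#' For every query flanking gene, reports the maximum CDS identity and the
#' maximum protein identity (gap-excluded, global alignment) over all
#' reference genes, and calls the gene syntenic under the thresholds.
#' The result is invariant to reference ordering, and the per-gene maxima
#' can only grow as the reference grows (pooling property).
#'
#' @param query A `synteny_neighborhood`.
#' @param reference A `synteny_neighborhood` or a pooled gene table (e.g.
#'   from [pooled_reference()]).
#' @param thresholds See [default_synteny_thresholds()].
#' @return data.frame with one row per query flanking gene: `query_gene`,
#'   `best_reference_gene` (argmax of protein identity), `cds_identity`,
#'   `protein_identity`, `protein_coverage`, `is_syntenic`.
#' @export
score_neighborhoods <- function(query, reference,
                                thresholds = default_synteny_thresholds()) {
  qf <- .flanking_of(query)
  rf <- .flanking_of(reference)
  if (nrow(qf) == 0L || nrow(rf) == 0L) stop("empty neighborhood")
  q_prot <- vapply(qf$cds, translate_cds, character(1))
  r_prot <- vapply(rf$cds, translate_cds, character(1))
  psc <- default_scoring("protein")
  pb <- batch_identity_cpp(q_prot, r_prot, psc$matrix,
                           paste0(rownames(psc$matrix), collapse = ""),
                           psc$gap_open, psc$gap_extend)
  dsc <- default_scoring("dna")
  db <- batch_identity_cpp(toupper(qf$cds), toupper(rf$cds), dsc$matrix,
                           paste0(rownames(dsc$matrix), collapse = ""),
                           dsc$gap_open, dsc$gap_extend)
  best_j <- max.col(pb$identity, ties.method = "first")
  pick <- cbind(seq_len(nrow(qf)), best_j)
  out <- data.frame(query_gene = qf$gene_id,
                    best_reference_gene = rf$gene_id[best_j],
                    cds_identity = apply(db$identity, 1L, max),
                    protein_identity = pb$identity[pick],
                    protein_coverage = pb$coverage[pick],
                    stringsAsFactors = FALSE)
  out$is_syntenic <- out$protein_identity >= thresholds$protein &
    out$protein_coverage >= thresholds$coverage &
    out$cds_identity >= thresholds$cds
  attr(out, "thresholds") <- thresholds
  out
}

#' Pool flanking genes from several neighborhoods into one reference
#'
#' Concatenates and de-duplicates (by `gene_id`) the flanking genes, e.g. to
#' combine the focal-gene-proximal genes of all tetrapod species into a more
#' sensitive reference for scans against distant genomes.
#'
#' @param neighborhoods List of `synteny_neighborhood` objects (length >= 1).
#' @return Gene table usable as `reference` in [score_neighborhoods()].
#' @export
pooled_reference <- function(neighborhoods) {
  if (length(neighborhoods) == 0L) stop("need at least one neighborhood")
  all <- do.call(rbind, lapply(neighborhoods, .flanking_of))
  all[!duplicated(all$gene_id), , drop = FALSE]
}

#' Syntenic-gene counts around two loci and their ratio
#'
#' @param query_a_matches,query_b_matches Match tables from
#'   [score_neighborhoods()] produced under the same thresholds.
#' @return List with `count_a`, `count_b`, `ratio` (NA when `count_b` is 0).
#' @export
synteny_count_ratio <- function(query_a_matches, query_b_matches) {
  ca <- sum(query_a_matches$is_syntenic)
  cb <- sum(query_b_matches$is_syntenic)
  list(count_a = ca, count_b = cb,
       ratio = if (cb > 0L) ca / cb else NA_real_)
}

## ---- annotation I/O -----------------------------------------------------

#' Read a BED-like gene table with a companion CDS FASTA
#'
#' Six tab-separated columns (chrom, start0, end, gene_id, score, strand;
#' BED-style 0-based half-open coordinates, converted to 1-based inclusive)
#' plus a FASTA of coding sequences keyed by gene_id.
#'
#' @param bed_path TSV file.
#' @param fasta_path CDS FASTA keyed by gene_id.
#' @param species Species label attached to every record.
#' @return Gene table data.frame.
#' @export
read_gene_table <- function(bed_path, fasta_path, species = NA_character_) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("chrom", "start0", "end", "gene_id",
                                         "score", "strand"))
  cds <- read_fasta(fasta_path, type = "dna")
  miss <- setdiff(bed$gene_id, names(cds))
  if (length(miss) > 0L)
    stop("CDS missing for genes: ", paste(utils::head(miss, 5), collapse = ", "))
  out <- data.frame(gene_id = bed$gene_id, species = species,
                    chrom = as.character(bed$chrom),
                    start = bed$start0 + 1L, end = bed$end,
                    strand = bed$strand, cds = unname(cds[bed$gene_id]),
                    stringsAsFactors = FALSE)
  .check_gene_table(out)
}

#' Write a gene table as BED-like TSV plus CDS FASTA
#'
#' @param genes Gene table data.frame.
#' @param bed_path Output TSV path.
#' @param fasta_path Output FASTA path.
#' @export
write_gene_table <- function(genes, bed_path, fasta_path) {
  genes <- .check_gene_table(genes)
  bed <- data.frame(chrom = genes$chrom, start0 = genes$start - 1L,
                    end = genes$end, gene_id = genes$gene_id, score = 0L,
                    strand = genes$strand)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_fasta(stats::setNames(genes$cds, genes$gene_id), fasta_path)
  invisible(bed_path)
}

#' Read gene records from GFF3 plus a genome FASTA
#'
#' Extracts gene-level records, stitching CDS features in coordinate order
#' (reverse-complemented on the minus strand). Requires the `rtracklayer`
#' package.
#'
#' @param gff_path GFF3 file with gene/mRNA/CDS features.
#' @param genome_fasta FASTA of the chromosome/contig sequences.
#' @param species Species label.
#' @return Gene table data.frame.
#' @export
read_gff3_genes <- function(gff_path, genome_fasta, species = NA_character_) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gff3_genes requires the rtracklayer package")
  gr <- rtracklayer::import(gff_path)
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genes <- gr[gr$type == "gene"]
  cds <- gr[gr$type == "CDS"]
  ids <- as.character(genes$ID)
  get_cds <- function(gid) {
    # CDS features point at their gene via Parent (mRNA id prefixed with gid)
    own <- cds[vapply(cds$Parent, function(p)
      any(startsWith(as.character(p), gid)), logical(1))]
    own <- own[order(GenomicRanges::start(own))]
    if (length(own) == 0L) return(NA_character_)
    chrom <- as.character(GenomicRanges::seqnames(own))[1L]
    pieces <- vapply(seq_along(own), function(k)
      as.character(Biostrings::subseq(genome[[chrom]],
                                      GenomicRanges::start(own)[k],
                                      GenomicRanges::end(own)[k])),
      character(1))
    s <- paste0(pieces, collapse = "")
    if (as.character(BiocGenerics::strand(own))[1L] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  out <- data.frame(gene_id = ids, species = species,
                    chrom = as.character(GenomicRanges::seqnames(genes)),
                    start = GenomicRanges::start(genes),
                    end = GenomicRanges::end(genes),
                    strand = as.character(BiocGenerics::strand(genes)),
                    cds = vapply(ids, get_cds, character(1)),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$cds), , drop = FALSE]
  .check_gene_table(out)
}
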