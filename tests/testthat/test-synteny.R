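# build a gene table of n evenly spaced genes on one chromosome
even_genome <- function(n, spacing, gene_len = 300, chrom = "chr1") {
  starts <- 1L + spacing * (seq_len(n) - 1L)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), species = "test",
             chrom = chrom, start = starts, end = starts + gene_len - 1L,
             strand = "+", cds = vapply(seq_len(n), function(i)
               random_cds(gene_len / 3), character(1)),
             stringsAsFactors = FALSE)
}

test_that("neighborhood respects the gene-count cap", {
  set.seed(51)
  g <- even_genome(100, 10000)
  nb <- neighborhood(g, "g050", n_genes = 30, window_bp = 1.5e6)
  expect_equal(sum(nb$flanking$side == "upstream"), 30)
  expect_equal(sum(nb$flanking$side == "downstream"), 30)
  expect_false("g050" %in% nb$flanking$gene_id)
})

test_that("neighborhood respects the bp-window cap", {
  set.seed(52)
  g <- even_genome(100, 100000)
  nb <- neighborhood(g, "g050", n_genes = 30, window_bp = 1.5e6)
  expect_equal(sum(nb$flanking$side == "upstream"), 15)
  expect_equal(sum(nb$flanking$side == "downstream"), 15)
})

test_that("neighborhood handles chromosome edges and strand labels", {
  set.seed(53)
  g <- even_genome(50, 10000)
  nb <- neighborhood(g, "g001", n_genes = 30)
  expect_equal(sum(nb$flanking$side == "upstream"), 0)
  expect_equal(sum(nb$flanking$side == "downstream"), 30)
  # a minus-strand focal flips side labels
  g$strand[1] <- "-"
  nb2 <- neighborhood(g, "g001", n_genes = 30)
  expect_equal(sum(nb2$flanking$side == "upstream"), 30)
  expect_error(neighborhood(g, "nope"), "not found")
})

test_that("neighborhood output is independent of input row order", {
  set.seed(54)
  g <- even_genome(60, 20000)
  nb1 <- neighborhood(g, "g030")
  nb2 <- neighborhood(g[sample(nrow(g)), ], "g030")
  expect_equal(nb1$flanking$gene_id, nb2$flanking$gene_id)
})

test_that("an exact copy in the reference scores identity 1 and syntenic", {
  set.seed(55)
  ga <- even_genome(11, 10000)
  gb <- even_genome(11, 10000)
  gb$gene_id <- sub("^g", "r", gb$gene_id)
  gb$cds[4] <- ga$cds[7]  # plant an exact copy
  na <- neighborhood(ga, "g006", n_genes = 5)
  nb <- neighborhood(gb, "r006", n_genes = 5)
  m <- score_neighborhoods(na, nb)
  row <- m[m$query_gene == "g007", ]
  expect_equal(row$cds_identity, 1.0)
  expect_equal(row$protein_identity, 1.0)
  expect_identical(row$best_reference_gene, "r004")
  expect_true(row$is_syntenic)
})

test_that("scores are invariant to reference order and grow under pooling", {
  set.seed(56)
  ga <- even_genome(7, 10000)
  gb <- even_genome(7, 10000)
  gb$gene_id <- sub("^g", "r", gb$gene_id)
  na <- neighborhood(ga, "g004", n_genes = 3)
  nb <- neighborhood(gb, "r004", n_genes = 3)
  m1 <- score_neighborhoods(na, nb)
  shuffled <- nb
  shuffled$flanking <- nb$flanking[sample(nrow(nb$flanking)), ]
  m2 <- score_neighborhoods(na, shuffled)
  m2 <- m2[match(m1$query_gene, m2$query_gene), ]
  expect_equal(m1$cds_identity, m2$cds_identity)
  expect_equal(m1$protein_identity, m2$protein_identity)
  # pooling a second neighborhood can only raise the per-gene maxima
  gc_ <- even_genome(7, 10000)
  gc_$gene_id <- sub("^g", "q", gc_$gene_id)
  nc <- neighborhood(gc_, "q004", n_genes = 3)
  pooled <- pooled_reference(list(nb, nc))
  m3 <- score_neighborhoods(na, pooled)
  m3 <- m3[match(m1$query_gene, m3$query_gene), ]
  expect_true(all(m3$cds_identity >= m1$cds_identity))
  expect_true(all(m3$protein_identity >= m1$protein_identity))
})

test_that("pooled references de-duplicate by gene id", {
  set.seed(57)
  g <- even_genome(7, 10000)
  nb <- neighborhood(g, "g004", n_genes = 3)
  expect_equal(nrow(pooled_reference(list(nb))), nrow(nb$flanking))
  expect_equal(nrow(pooled_reference(list(nb, nb))), nrow(nb$flanking))
})

test_that("synteny counts and ratio summarize match tables", {
  mk <- function(flags) data.frame(is_syntenic = flags)
  r <- synteny_count_ratio(mk(rep(c(TRUE, FALSE), c(25, 5))),
                           mk(rep(c(TRUE, FALSE), c(17, 13))))
  expect_equal(r$count_a, 25)
  expect_equal(r$count_b, 17)
  expect_equal(r$ratio, 25 / 17)
  r0 <- synteny_count_ratio(mk(FALSE), mk(FALSE))
  expect_true(is.na(r0$ratio))
})

test_that("BED-like gene tables round-trip with their CDS FASTA", {
  set.seed(58)
  g <- even_genome(5, 10000)
  bed <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fasta")
  write_gene_table(g, bed, fa)
  back <- read_gene_table(bed, fa, species = "test")
  expect_equal(back$gene_id, g$gene_id)
  expect_equal(back$start, g$start)
  expect_equal(back$end, g$end)
  expect_equal(back$cds, g$cds)
})

test_that("GFF3 genes are stitched strand-aware", {
  # two genes, one on the minus strand with a split CDS
  genome <- c(chr1 = paste0("AAAA", "ATGGCTGAA", "TTTT",
                            as.character(Biostrings::reverseComplement(
                              Biostrings::DNAString("ATGCCCAAAGGG"))), "CC"))
  fa <- tempfile(fileext = ".fa")
  write_fasta(genome, fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t5\t13\t.\t+\t.\tID=gplus",
    "chr1\ttest\tmRNA\t5\t13\t.\t+\t.\tID=gplus.t1;Parent=gplus",
    "chr1\ttest\tCDS\t5\t13\t.\t+\t0\tID=gplus.c1;Parent=gplus.t1",
    "chr1\ttest\tgene\t18\t29\t.\t-\t.\tID=gminus",
    "chr1\ttest\tmRNA\t18\t29\t.\t-\t.\tID=gminus.t1;Parent=gminus",
    "chr1\ttest\tCDS\t24\t29\t.\t-\t0\tID=gminus.c1;Parent=gminus.t1",
    "chr1\ttest\tCDS\t18\t23\t.\t-\t2\tID=gminus.c2;Parent=gminus.t1"),
    gff)
  g <- read_gff3_genes(gff, fa, species = "toy")
  expect_equal(nrow(g), 2)
  expect_equal(g$cds[g$gene_id == "gplus"], "ATGGCTGAA")
  expect_equal(g$cds[g$gene_id == "gminus"], "ATGCCCAAAGGG")
  expect_equal(g$strand, c("+", "-"))
})
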