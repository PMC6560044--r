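test_that("codon counts cover sense codons and drop the terminal stop", {
  cc <- codon_counts("ATGGCTGCCGCT")
  expect_equal(unname(cc[c("ATG", "GCT", "GCC")]), c(1, 2, 1))
  expect_equal(sum(cc), 4)
  expect_length(cc, 61)
  expect_equal(sum(codon_counts("ATG")), 1)
  cc <- codon_counts("ATGTAA")
  expect_equal(sum(cc), 1)
  expect_equal(unname(cc["ATG"]), 1)
})

test_that("raw frequencies divide by total codons", {
  p <- raw_frequencies(codon_counts("ATGGCTGCCGCT"))
  expect_equal(unname(p$frequencies[c("ATG", "GCT", "GCC")]),
               c(0.25, 0.5, 0.25))
  expect_equal(sum(p$frequencies), 1)
  expect_equal(unname(raw_frequencies(codon_counts("ATG"))$frequencies["ATG"]), 1)
  # pooling two genes equals counting their concatenation
  g1 <- random_cds(15); g2 <- random_cds(25)
  pooled <- group_profile(list(codon_counts(g1), codon_counts(g2)),
                          "raw_frequency")
  concat <- raw_frequencies(codon_counts(paste0(g1, g2)))
  expect_equal(pooled$frequencies, concat$frequencies)
})

test_that("amino-acid-specific frequencies are conditional probabilities", {
  p <- aa_specific_frequencies(codon_counts("ATGGCTGCCGCT"))
  expect_equal(unname(p$frequencies[c("GCT", "GCC", "GCA", "GCG")]),
               c(2 / 3, 1 / 3, 0, 0))
  expect_equal(unname(p$frequencies["ATG"]), 1)
  # absent amino acid: undefined, not zero
  expect_true(all(is.na(p$frequencies[c("AAA", "AAG")])))
  # per-amino-acid sums equal 1 for present amino acids
  set.seed(3)
  p <- aa_specific_frequencies(codon_counts(random_cds(200)))
  tab <- Biostrings::GENETIC_CODE[names(p$frequencies)]
  sums <- tapply(p$frequencies, tab, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
})

test_that("group profiles pool counts, not per-gene means", {
  g <- codon_counts(random_cds(30))
  expect_equal(group_profile(list(g), "aa_specific")$frequencies,
               aa_specific_frequencies(g)$frequencies)
  expect_equal(group_profile(list(g, g), "aa_specific")$frequencies,
               aa_specific_frequencies(g)$frequencies)
  expect_error(group_profile(list()), "empty")
  # per-gene-mean variant averages frequency vectors
  g2 <- codon_counts(random_cds(30))
  m <- group_profile(list(g, g2), "raw_frequency", method = "mean")
  expect_equal(m$frequencies,
               (raw_frequencies(g)$frequencies +
                  raw_frequencies(g2)$frequencies) / 2)
})

test_that("profile correlation drops undefined dimensions pairwise", {
  set.seed(9)
  p <- aa_specific_frequencies(codon_counts(random_cds(150)))
  self <- profile_correlation(p, p)
  expect_equal(self$r, 1.0)
  # single-codon amino acids are excluded under aa_specific
  expect_true(self$n_codons <= 59)
  # symmetry and order invariance
  q <- aa_specific_frequencies(codon_counts(random_cds(150)))
  expect_equal(profile_correlation(p, q)$r, profile_correlation(q, p)$r)
  # metric mismatch errors
  r <- raw_frequencies(codon_counts(random_cds(50)))
  expect_error(profile_correlation(p, r), "metric")
})

test_that("anti-profile on twofold families correlates at -1", {
  # restrict to twofold amino acids and flip the conditional frequencies
  two_aas <- c("N", "D", "C", "Q", "E", "H", "K", "F", "Y")
  codons <- unlist(lapply(two_aas, synonymous_codons))
  set.seed(15)
  counts <- codon_counts(random_cds(400))
  p <- aa_specific_frequencies(counts)
  anti <- p
  anti$frequencies[codons] <- 1 - anti$frequencies[codons]
  cr <- profile_correlation(p, anti, codon_filter = codons)
  expect_equal(cr$r, -1.0)
})

test_that("genes sampled from a profile correlate higher with it", {
  set.seed(21)
  gc_prof <- make_target_profile("gc", strength = 6)
  at_prof <- make_target_profile("at", strength = 6)
  hits <- vapply(1:25, function(i) {
    g <- sample_gene(default_protein(), gc_prof, bias_strength = 1)
    p <- aa_specific_frequencies(codon_counts(g))
    profile_correlation(p, gc_prof)$r > profile_correlation(p, at_prof)$r
  }, logical(1))
  expect_true(mean(hits) >= 0.95)
})

test_that("program benchmarking assigns generated genes to their program", {
  set.seed(27)
  gc_prof <- make_target_profile("gc", strength = 5)
  at_prof <- make_target_profile("at", strength = 5)
  prol <- lapply(1:12, function(i)
    codon_counts(sample_gene(default_protein(), gc_prof, 1)))
  names(prol) <- paste0("p", 1:12)
  diff <- lapply(1:12, function(i)
    codon_counts(sample_gene(default_protein(), at_prof, 1)))
  names(diff) <- paste0("d", 1:12)
  focal <- codon_counts(sample_gene(default_protein(), gc_prof, 1))
  b <- benchmark_gene(focal, prol, diff, gene_id = "focal")
  expect_identical(b$assignment, "proliferation")
  expect_true(b$r_vs_proliferation > b$r_vs_differentiation)
  # focal gene proportional to a group profile: r = 1 vs that group
  pool <- Reduce(`+`, prol)
  b2 <- benchmark_gene(pool * 2, prol, diff, gene_id = "poolcopy",
                       leave_one_out = FALSE)
  expect_equal(b2$r_vs_proliferation, 1.0)
  # identical program profiles: flagged ambiguous
  b3 <- benchmark_gene(focal, prol, prol, gene_id = "focal")
  expect_identical(b3$assignment, "ambiguous")
  # leave-one-out: member gene's own-group profile excludes it
  b4 <- benchmark_gene(prol[["p1"]], prol, diff, gene_id = "p1")
  expect_identical(b4$assignment, "proliferation")
})

test_that("Kazusa-style codon table round-trips bit-exactly", {
  set.seed(33)
  counts <- codon_counts(random_cds(3000))
  path <- tempfile(fileext = ".txt")
  write_codon_table(counts, path)
  prof <- read_codon_table(path)
  expect_equal(prof$counts, counts)
  # RNA spelling accepted
  expect_true(any(grepl("U", readLines(path))))
  # truncated table errors, naming missing codons
  lines <- readLines(path)
  writeLines(lines[-1], path)
  expect_error(read_codon_table(path), "missing codons")
})

test_that("gene-set list files round-trip and support comments", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# program genes", "geneA", "geneB  ", "", "geneC # inline"),
             path)
  expect_identical(read_gene_set(path), c("geneA", "geneB", "geneC"))
  write_gene_set(c("x", "y"), path)
  expect_identical(read_gene_set(path), c("x", "y"))
})

test_that("JS divergence separates distinct target profiles", {
  gc_prof <- make_target_profile("gc", strength = 4)
  at_prof <- make_target_profile("at", strength = 4)
  expect_equal(js_divergence(gc_prof, gc_prof), 0)
  expect_true(js_divergence(gc_prof, at_prof) >= 0.05)
})
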