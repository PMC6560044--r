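test_that("substitution score is mismatches over CDS length", {
  expect_equal(substitution_score("ATGGCT", "ATGGCC"), 1 / 6)
  expect_equal(substitution_score("ATGGCT", "ATGGCT"), 0)
  # depends only on the mismatch count, not which base changed
  expect_equal(substitution_score("ATGGCT", "ATGGCA"),
               substitution_score("ATGGCT", "ATGGCG"))
  # alternative denominators coincide for equal-length CDSs
  expect_equal(substitution_score("ATGGCT", "ATGGCC", "min_length"), 1 / 6)
  expect_equal(substitution_score("ATGGCT", "ATGGCC", "mean_length"), 1 / 6)
})

test_that("substitution score is consistent with gap-excluded identity", {
  set.seed(17)
  for (k in 1:10) {
    a <- random_cds(40)
    ev <- evolve_synonymous(a, 0.1, bias_strength = 0)
    aln <- codon_align(c(a = a, b = ev$cds))
    expect_equal(substitution_score(a, ev$cds),
                 1 - identity_gap_excluded(unname(aln$rows)))
  }
})

test_that("distance matrix is symmetric with planted distances", {
  g <- c(a = "ATGGCTGCT", b = "ATGGCTGCT", c = "ATGGCTGCT")
  expect_true(all(distance_matrix(g) == 0))
  # plant k = 2 substitutions in a length-30 CDS
  base <- "ATGGCTGCTGCAGCGAAAAAGCTGCTGCCC"
  mut <- base
  substr(mut, 6, 6) <- "A"; substr(mut, 9, 9) <- "A"
  d <- distance_matrix(c(x = base, y = mut))
  expect_equal(d["x", "y"], 2 / 30)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("site classification matches per-codon degeneracy", {
  aln <- codon_align(c(a = "GCTAATATG", b = "GCCAACATG", c = "GCAAATATG"))
  cls <- classify_sites(aln)
  expect_true(cls$is_fourfold[1])    # Ala column in all rows
  expect_true(cls$is_wobble[2])      # Asn: twofold wobble
  expect_false(cls$is_fourfold[2])
  expect_false(cls$is_wobble[3])     # Met: fold 1
  # brute-force agreement on random identical-protein alignments
  set.seed(23)
  for (k in 1:5) {
    prot <- translate_cds(random_cds(30))
    seqs <- vapply(1:3, function(i) sample_gene(prot, bias_strength = 0),
                   character(1))
    names(seqs) <- paste0("s", 1:3)
    aln <- codon_align(seqs)
    cls <- classify_sites(aln)
    m <- t(vapply(aln$rows, function(r)
      substring(r, 3 * seq_len(nchar(r) / 3) - 2, 3 * seq_len(nchar(r) / 3)),
      character(nchar(seqs[[1]]) / 3)))
    for (j in seq_len(ncol(m))) {
      folds <- vapply(m[, j], function(cd) oracle_fold(cd, 3), numeric(1))
      expect_equal(cls$is_fourfold[j], all(folds == 4), info = j)
      expect_equal(cls$is_wobble[j], all(folds >= 2), info = j)
    }
  }
})

test_that("conserved report counts absolutely conserved columns", {
  aln <- codon_align(c(a = "GCTGCA", b = "GCTGCC", c = "GCTGCG"))
  rep4 <- conserved_report(aln, "fourfold")
  expect_equal(rep4$conserved_count, 1)
  expect_equal(rep4$total_sites, 2)
  expect_equal(rep4$frequency, 0.5)
  # all rows identical: frequency 1
  aln <- codon_align(c(a = "GCTGCA", b = "GCTGCA"))
  expect_equal(conserved_report(aln, "third_position")$frequency, 1.0)
  # no sites of the requested class: flagged undefined, not silent zero
  aln <- codon_align(c(a = "ATGTGG", b = "ATGTGG"))
  rep0 <- conserved_report(aln, "fourfold")
  expect_true(rep0$undefined)
  expect_equal(rep0$total_sites, 0)
  expect_true(is.na(rep0$frequency))
})

test_that("conserved frequency is invariant to row order and renaming", {
  set.seed(31)
  prot <- translate_cds(random_cds(40))
  seqs <- vapply(1:4, function(i) sample_gene(prot, bias_strength = 0),
                 character(1))
  names(seqs) <- paste0("s", 1:4)
  f1 <- conserved_report(codon_align(seqs), "fourfold")$frequency
  shuffled <- seqs[c(3, 1, 4, 2)]
  names(shuffled) <- paste0("renamed", 1:4)
  f2 <- conserved_report(codon_align(shuffled), "fourfold")$frequency
  expect_equal(f1, f2)
})

test_that("conserved frequency decreases with substitution pressure", {
  set.seed(37)
  freqs <- vapply(c(0.02, 0.2, 0.8), function(bl) {
    anc <- sample_gene(default_protein(), bias_strength = 0)
    tips <- vapply(1:6, function(i)
      evolve_synonymous(anc, bl, bias_strength = 0)$cds, character(1))
    names(tips) <- paste0("t", 1:6)
    conserved_report(codon_align(tips), "fourfold")$frequency
  }, numeric(1))
  expect_true(freqs[1] > freqs[2])
  expect_true(freqs[2] > freqs[3])
})

test_that("frequency ratio divides frequencies and guards zero", {
  r <- function(f, tot = 100) structure(
    list(group_name = "g", site_class = "fourfold",
         conserved_count = round(f * tot), total_sites = tot,
         frequency = f, undefined = FALSE), class = "conservation_report")
  expect_equal(freq_ratio(r(0.5), r(0.25)), 2.0)
  expect_equal(freq_ratio(r(0.3), r(0.3)), 1.0)
  expect_error(freq_ratio(r(0.5), r(0)), "zero")
})

test_that("gc3 counts G/C at third positions, excluding the stop", {
  expect_equal(gc3("ATGGCT"), 0.5)
  expect_equal(gc3("ATGGCC"), 1.0)
  expect_equal(gc3("ATGGCA"), 0.5)
  expect_equal(gc3("ATGGCCTAA"), 1.0)  # stop codon TAA not counted
})

test_that("rank-sum test matches the exact permutation distribution", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$u_statistic, 0)
  expect_equal(rs$p_value, 0.1)  # 2/20 arrangements as extreme
  set.seed(41)
  for (k in 1:30) {
    n_a <- sample(2:7, 1); n_b <- sample(2:7, 1)
    vals <- sample(1000, n_a + n_b)  # tie-free
    a <- vals[seq_len(n_a)]; b <- vals[-seq_len(n_a)]
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(rank_sum_test(a, b, alt)$p_value,
                   oracle_ranksum_p(a, b, alt),
                   info = paste(k, alt))
    }
  }
})

test_that("rank-sum degenerate and tied inputs are handled", {
  expect_warning(rs <- rank_sum_test(c(1, 1, 1), c(1, 1)), "identical")
  expect_equal(rs$p_value, 1)
  rs <- rank_sum_test(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_false(rs$exact)
  expect_true(rs$p_value > 0 && rs$p_value <= 1)
})

test_that("identical multisets give a near-1 two-sided p-value", {
  rs <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(rs$p_value >= 0.99)
})
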