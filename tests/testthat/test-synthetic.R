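test_that("sampled genes always retranslate to the input protein", {
  prot <- default_protein()
  expect_equal(nchar(prot), 136)
  gc_prof <- make_target_profile("gc", strength = 4)
  for (bias in c(0, 0.5, 1)) {
    cds <- sample_gene(prot, gc_prof, bias, seed = 101)
    expect_identical(translate_cds(cds), prot)
  }
})

test_that("bias_strength 1 with a concentrated profile is deterministic", {
  # profile concentrated on GCT for alanine
  sc <- sense_codons()
  counts <- stats::setNames(rep(1L, length(sc)), sc)
  counts[c("GCA", "GCC", "GCG")] <- 0L
  counts["GCT"] <- 100L
  prof <- aa_specific_frequencies(counts)
  cds <- sample_gene("MAAAA", prof, bias_strength = 1, seed = 1)
  expect_identical(cds, "ATGGCTGCTGCTGCT")
})

test_that("bias_strength 0 gives uniform synonym usage", {
  set.seed(71)
  cds <- paste0(vapply(1:2500, function(i)
    sample_gene("LLLL", bias_strength = 0), character(1)), collapse = "")
  counts <- codon_counts(cds)
  leu <- counts[synonymous_codons("L")]
  gof <- stats::chisq.test(leu)
  expect_gt(gof$p.value, 0.001)
})

test_that("synonymous evolution preserves the protein and records truth", {
  set.seed(73)
  anc <- sample_gene(default_protein(), bias_strength = 0)
  ev0 <- evolve_synonymous(anc, 0)
  expect_identical(ev0$cds, anc)
  expect_equal(ev0$n_events, 0)
  ev <- evolve_synonymous(anc, 0.3, bias_strength = 0)
  expect_identical(translate_cds(ev$cds), default_protein())
  expect_identical(replay_substitutions(anc, ev$events), ev$cds)
})

test_that("substitution scores grow with branch length", {
  set.seed(79)
  mean_score <- vapply(c(0.01, 0.05, 0.25), function(bl) {
    mean(vapply(1:40, function(i) {
      anc <- sample_gene(default_protein(), bias_strength = 0)
      substitution_score(anc, evolve_synonymous(anc, bl)$cds)
    }, numeric(1)))
  }, numeric(1))
  expect_true(mean_score[1] < mean_score[2])
  expect_true(mean_score[2] < mean_score[3])
})

test_that("family simulation is deterministic and truth replays", {
  cfg <- family_config(seed = 91, n_tips = 4)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$paralogs, f2$paralogs)
  for (p in names(f1$paralogs)) {
    anc <- f1$truth[[p]]$ancestor
    for (tip in names(f1$paralogs[[p]])) {
      expect_identical(
        replay_substitutions(anc, f1$truth[[p]]$events[[tip]]),
        f1$paralogs[[p]][[tip]])
      expect_identical(translate_cds(f1$paralogs[[p]][[tip]]),
                       cfg$protein)
    }
  }
  # written outputs are byte-identical under the same seed
  d1 <- tempfile(); d2 <- tempfile()
  write_simulated_family(f1, d1)
  write_simulated_family(f2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("newick trees drive the family simulation", {
  cfg <- family_config(seed = 93,
                       tree = "((a:0.02,b:0.02):0.05,c:0.2,d:0.2);")
  fam <- simulate_family(cfg)
  expect_setequal(names(fam$paralogs$slow), c("a", "b", "c", "d"))
  for (tip in c("a", "b", "c", "d"))
    expect_identical(
      replay_substitutions(fam$truth$slow$ancestor,
                           fam$truth$slow$events[[tip]]),
      fam$paralogs$slow[[tip]])
  # shallow tips are closer to each other than deep tips are
  set.seed(1)
  d <- distance_matrix(fam$paralogs$fast)
  expect_true(d["a", "b"] <= d["c", "d"] + 0.2)
})

test_that("zero-branch star families are identical to the ancestor", {
  fam <- simulate_family(family_config(seed = 95, n_tips = 3,
                                       branch_length = 0))
  for (p in names(fam$paralogs))
    expect_true(all(fam$paralogs[[p]] == fam$truth[[p]]$ancestor))
})

test_that("neighborhood simulation plants the configured orthologs", {
  nbc <- neighborhood_config(seed = 97, n_orthologs = 4, n_decoys = 6)
  sim <- simulate_neighborhoods(nbc)
  expect_equal(nrow(sim$truth), 4)
  expect_equal(nrow(sim$genome_a), 11)  # 4 + 6 flanking + focal
  expect_true("focal" %in% sim$genome_a$gene_id)
  # determinism
  sim2 <- simulate_neighborhoods(nbc)
  expect_identical(sim$genome_a, sim2$genome_a)
  expect_identical(sim$genome_b, sim2$genome_b)
  # decoys only
  sim0 <- simulate_neighborhoods(neighborhood_config(seed = 98,
                                                     n_orthologs = 0,
                                                     n_decoys = 5))
  expect_equal(nrow(sim0$truth), 0)
})

test_that("UTR evolution matches its configured rates", {
  u <- random_utr(500, seed = 99)
  expect_identical(evolve_utr(u, 0, 0, seed = 1)$utr, u)
  # indels only: gap-excluded identity stays exactly 1
  ev <- evolve_utr(u, sub_rate = 0, indel_rate = 0.01, mean_indel_len = 4,
                   seed = 2)
  expect_true(nrow(ev$indels) > 0)
  expect_equal(utr3_similarity(u, ev$utr), 1.0)
  # substitutions only: identity near 1 - rate (binomial CI at n = 500)
  ev <- evolve_utr(u, sub_rate = 0.25, indel_rate = 0, seed = 3)
  id <- utr3_similarity(u, ev$utr)
  expect_true(abs(id - 0.75) < 3 * sqrt(0.25 * 0.75 / 500) + 0.01)
})
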