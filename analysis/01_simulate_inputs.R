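#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by all downstream analysis
# scripts: two ortholog panels (a slow- and a fast-evolving duplicate gene
# encoding the same protein) over a tree with shallow/intermediate/deep
# tips, program-biased gene sets, a genome-wide codon usage table, two gene
# neighborhoods with planted orthologs, and a set of evolved 3'UTRs.
# Everything is seeded; rerunning reproduces the same bytes.

suppressMessages(library(dupcodon))
data_dir <- file.path("results", "data")
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 42L

## ortholog panels: nested divergence depths (4 shallow, 4 intermediate,
## 4 deep tips), paralog synonymous rates differing fivefold
tree <- paste0("((p1:0.01,p2:0.01,p3:0.01,p4:0.01):0.01,",
               "(m1:0.08,m2:0.08,m3:0.08,m4:0.08):0.02,",
               "t1:0.3,t2:0.3,t3:0.3,t4:0.3);")
fam <- simulate_family(family_config(seed = seed, tree = tree))
write_simulated_family(fam, data_dir)
cat("ortholog panels:", paste(names(fam$paralogs), collapse = ", "),
    "with", length(fam$paralogs[[1]]), "tips each\n")

groups <- list(shallow = paste0("p", 1:4),
               intermediate = c(paste0("p", 1:4), paste0("m", 1:4)),
               deep = c(paste0("p", 1:4), paste0("m", 1:4), paste0("t", 1:4)))
for (g in names(groups))
  write_gene_set(groups[[g]], file.path(data_dir, paste0("group_", g, ".txt")))

## program gene sets: GC3-preferring vs AT3-preferring codon-usage targets
set.seed(seed)
gc_prof <- make_target_profile("gc", 4)
at_prof <- make_target_profile("at", 4)
prol <- vapply(1:30, function(i)
  sample_gene(default_protein(), gc_prof, 1), character(1))
names(prol) <- sprintf("prolif_%02d", 1:30)
diffg <- vapply(1:30, function(i)
  sample_gene(default_protein(), at_prof, 1), character(1))
names(diffg) <- sprintf("differ_%02d", 1:30)
write_fasta(prol, file.path(data_dir, "proliferation.fasta"))
write_fasta(diffg, file.path(data_dir, "differentiation.fasta"))
cat("program gene sets: 30 + 30 genes, JS divergence of targets =",
    round(js_divergence(gc_prof, at_prof), 3), "\n")

## genome-wide codon usage: pooled counts of genes drawn from the mixture
## of the two program targets (the broad-expression background)
gw_target <- aa_specific_frequencies(gc_prof$counts + at_prof$counts,
                                     "genome-wide-target")
gw_counts <- Reduce(`+`, lapply(1:200, function(i)
  codon_counts(sample_gene(default_protein(), gw_target, 1))))
write_codon_table(gw_counts, file.path(data_dir, "codon_table.txt"))
cat("genome-wide codon table:", sum(gw_counts), "codons pooled\n")

## neighborhoods: 10 planted orthologs among 20 decoys around one focal gene
sim <- simulate_neighborhoods(neighborhood_config(seed = seed,
                                                  syn_divergence = 0.2,
                                                  nonsyn_rate = 0.05))
write_gene_table(sim$genome_a, file.path(data_dir, "genome_a.tsv"),
                 file.path(data_dir, "genome_a.fasta"))
write_gene_table(sim$genome_b, file.path(data_dir, "genome_b.tsv"),
                 file.path(data_dir, "genome_b.fasta"))
write_tsv_meta(sim$truth, file.path(data_dir, "neighborhood_truth.tsv"),
               list(planted_orthologs = nrow(sim$truth)))
cat("neighborhoods:", nrow(sim$genome_a) - 1, "flanking genes per genome,",
    nrow(sim$truth), "planted ortholog pairs\n")

## 3'UTRs: one ancestral UTR plus divergent copies (substitutions and
## indels), and one unrelated UTR
u <- random_utr(500, seed = seed)
utrs <- c(
  anc = u,
  subs_only = evolve_utr(u, 0.15, 0, seed = seed + 1)$utr,
  indels_only = evolve_utr(u, 0, 0.02, 4, seed = seed + 2)$utr,
  both = evolve_utr(u, 0.15, 0.02, 4, seed = seed + 3)$utr,
  unrelated = random_utr(500, seed = seed + 4))
write_fasta(utrs, file.path(data_dir, "utrs.fasta"))
cat("3'UTR set:", length(utrs), "sequences of ~500 bp\n")
cat("inputs written under", data_dir, "\n")
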