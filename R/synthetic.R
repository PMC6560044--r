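## Seeded synthetic-data generator with planted truth.
##
## Emulates the study conditions this pipeline was built for: panels of
## orthologous CDSs that encode one fixed protein and diverge only at
## synonymous sites (with paralog-specific rates and codon-bias targets),
## program-biased gene sets for codon-usage benchmarking, gene neighborhoods
## with planted orthologs among random decoys for the synteny scan, and
## 3'UTRs evolved with substitutions and indels. Every generator is
## deterministic given its seed; per-gene RNG substreams are derived from the
## seed so outputs do not depend on iteration order. Substitutions operate in
## codon space (a codon is resampled among its synonyms), which guarantees
## protein invariance by construction at the cost of not modelling
## transition/transversion bias.

# Synthetic 136-residue protein of realistic vertebrate amino-acid
# composition (matches the length of the histone variant the analysis is
# modelled on; it is NOT a database sequence).
.SYNTHETIC_PROTEIN <- paste0(
  "MQAFIRGDGAFYFAMPRGMSRFAASMVRSTYICQIAVQVYQFDCKYGPKGNHEYSGHTGLRFCATYFLYE",
  "SAYLGYTKDRESNEDFGYDMHRQVVVKSLSKKEPLHFQCYVTASMLDQNDKYPERAAKLRALKCPM")

#' Default synthetic protein
#'
#' A fixed 136-residue synthetic amino-acid sequence of realistic
#' composition, used as the shared product of simulated duplicate-gene
#' families.
#'
#' @return One-letter amino-acid string of length 136.
#' @export
default_protein <- function() .SYNTHETIC_PROTEIN

# deterministic per-item substream seed, kept below 2^31
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 2654435) %% 2147483647
}

.with_seed <- function(seed, expr) {
  set.seed(as.integer(seed))
  expr
}

#' Synthetic codon-bias target profile
#'
#' Builds an amino-acid-specific target profile that prefers codons ending in
#' G/C (`"gc"`), in A/T (`"at"`), or no codon (`"uniform"`). `strength` is
#' the relative weight of a preferred codon over a non-preferred one within
#' each synonym family.
#'
#' @param prefer `"gc"`, `"at"` or `"uniform"`.
#' @param strength Preference weight (>= 1); 1 is uniform.
#' @return `codon_usage_profile` with metric `"aa_specific"` (pseudo-counts
#'   scaled to 1000 per codon unit, so profiles can be compared with
#'   [js_divergence()]).
#' @export
make_target_profile <- function(prefer = c("gc", "at", "uniform"),
                                strength = 4) {
  prefer <- match.arg(prefer)
  sc <- sense_codons()
  third <- substr(sc, 3L, 3L)
  w <- rep(1, length(sc))
  if (prefer == "gc") w[third %in% c("G", "C")] <- strength
  if (prefer == "at") w[third %in% c("A", "T")] <- strength
  counts <- stats::setNames(round(1000 * w), sc)
  aa_specific_frequencies(counts, source = paste0("target-", prefer))
}

# conditional synonym-choice probabilities for one amino acid under a
# mixture of the target profile and the uniform-over-synonyms distribution
.syn_probs <- function(syns, profile, bias_strength) {
  unif <- rep(1 / length(syns), length(syns))
  if (is.null(profile) || bias_strength == 0) return(unif)
  f <- profile$frequencies[syns]
  if (anyNA(f) || sum(f) == 0)
    stop("target profile undefined for amino acid of codons: ",
         paste(syns, collapse = "/"))
  bias_strength * (f / sum(f)) + (1 - bias_strength) * unif
}

#' Sample a CDS for a protein under a codon-bias target
#'
#' Each codon is drawn from the mixture
#' `bias_strength * profile + (1 - bias_strength) * uniform-over-synonyms`,
#' so the emitted CDS always translates back to `protein` exactly.
#'
#' @param protein One-letter amino-acid string (no stops).
#' @param profile Optional `aa_specific` target profile.
#' @param bias_strength Mixing weight in `[0, 1]` toward the target.
#' @param seed Optional seed for this draw.
#' @return CDS string (no stop codon appended).
#' @export
sample_gene <- function(protein, profile = NULL, bias_strength = 0.5,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  aas <- strsplit(toupper(protein), "")[[1L]]
  codons <- vapply(aas, function(aa) {
    syns <- synonymous_codons(aa)
    if (length(syns) == 1L) return(syns)
    sample(syns, 1L, prob = .syn_probs(syns, profile, bias_strength))
  }, character(1))
  paste0(codons, collapse = "")
}

#' Evolve a CDS at synonymous sites only
#'
#' Draws `Poisson(branch_length * S)` substitution events, where S is the
#' number of codons with at least one synonym, and at each event resamples
#' one such codon among its synonyms from the biased mixture. The encoded
#' protein is invariant by construction; every event is recorded so the tip
#' can be replayed from the ancestor.
#'
#' @param cds Translatable CDS.
#' @param branch_length Expected substitutions per synonymous site.
#' @param profile,bias_strength Codon-bias target (see [sample_gene()]).
#' @param seed Optional seed.
#' @return List: `cds` (evolved), `events` (data.frame codon_index/from/to),
#'   `n_events`, `n_changed` (events that altered the codon).
#' @export
evolve_synonymous <- function(cds, branch_length, profile = NULL,
                              bias_strength = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(branch_length >= 0)
  codons <- split_codons(cds)
  tab <- .genetic_code()
  aas <- tab[codons]
  eligible <- which(aas != "*" &
                    vapply(aas, function(a)
                      a != "*" && length(synonymous_codons(a)) > 1L,
                      logical(1)))
  n_events <- stats::rpois(1L, branch_length * length(eligible))
  ev_idx <- if (n_events > 0L && length(eligible) > 0L)
    sample(eligible, n_events, replace = TRUE) else integer(0)
  from <- character(0); to <- character(0)
  for (i in ev_idx) {
    syns <- synonymous_codons(aas[[i]])
    new <- sample(syns, 1L, prob = .syn_probs(syns, profile, bias_strength))
    from <- c(from, codons[i]); to <- c(to, new)
    codons[i] <- new
  }
  events <- data.frame(codon_index = ev_idx, from = from, to = to,
                       stringsAsFactors = FALSE)
  list(cds = paste0(codons, collapse = ""), events = events,
       n_events = length(ev_idx),
       n_changed = sum(events$from != events$to))
}

#' Replay recorded substitution events onto an ancestor CDS
#'
#' @param cds Ancestor CDS.
#' @param events Event table from [evolve_synonymous()].
#' @return The descendant CDS.
#' @export
replay_substitutions <- function(cds, events) {
  codons <- split_codons(cds)
  for (k in seq_len(nrow(events))) {
    i <- events$codon_index[k]
    if (codons[i] != events$from[k])
      stop("event ", k, " does not match the current codon at ", i)
    codons[i] <- events$to[k]
  }
  paste0(codons, collapse = "")
}

#' Configuration for a simulated duplicate-gene family
#'
#' Defaults emulate the study conditions: one fixed 136-residue protein,
#' an 8-species star tree with branch length 0.05 expected substitutions per
#' synonymous site, and two paralogs whose synonymous rates differ fivefold
#' (the "slow" copy under stronger purifying selection at synonymous sites).
#'
#' @param seed Integer seed.
#' @param protein Shared protein product.
#' @param n_tips Number of species (star tree), ignored if `tree` given.
#' @param tree Optional newick string with branch lengths (expected
#'   synonymous substitutions per site).
#' @param branch_length Star-tree tip branch length.
#' @param paralog_rates Named per-paralog rate multipliers.
#' @param target_profiles Optional named list of `aa_specific` profiles, one
#'   per paralog (NULL entries mean uniform synonym choice).
#' @param bias_strength Mixing weight toward the target profile.
#' @return List of class `family_config`.
#' @export
family_config <- function(seed = 1L, protein = default_protein(),
                          n_tips = 8L, tree = NULL, branch_length = 0.05,
                          paralog_rates = c(slow = 1, fast = 5),
                          target_profiles = NULL, bias_strength = 0) {
  stopifnot(bias_strength >= 0, bias_strength <= 1, all(paralog_rates >= 0))
  structure(list(seed = seed, protein = protein, n_tips = n_tips,
                 tree = tree, branch_length = branch_length,
                 paralog_rates = paralog_rates,
                 target_profiles = target_profiles,
                 bias_strength = bias_strength),
            class = "family_config")
}

#' Simulate ortholog panels for a duplicate-gene family
#'
#' For each paralog, samples one ancestral CDS for the shared protein and
#' evolves it to every tree tip at synonymous sites only, with the paralog's
#' rate multiplier. All emitted CDSs translate to the configured protein.
#'
#' @param config A [family_config()].
#' @return List of class `simulated_family`: `paralogs` (named list of named
#'   CDS vectors, one per tip), `truth` (ancestors and per-tip event tables),
#'   `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "family_config"))
  if (!is.null(config$tree)) {
    tr <- ape::read.tree(text = config$tree)
    if (is.null(tr)) stop("invalid newick tree")
    tips <- tr$tip.label
  } else {
    tr <- NULL
    tips <- sprintf("sp%02d", seq_len(config$n_tips))
  }
  paralogs <- names(config$paralog_rates)
  if (is.null(paralogs)) paralogs <- paste0("paralog", seq_along(config$paralog_rates))
  out <- list(); truth <- list()
  for (pi in seq_along(paralogs)) {
    pname <- paralogs[pi]
    rate <- config$paralog_rates[[pi]]
    prof <- config$target_profiles[[pname]]
    anc <- sample_gene(config$protein, prof, config$bias_strength,
                       seed = derive_seed(config$seed, pi * 1000L))
    if (is.null(tr)) {
      tip_seqs <- list(); tip_events <- list()
      for (ti in seq_along(tips)) {
        ev <- evolve_synonymous(anc, config$branch_length * rate, prof,
                                config$bias_strength,
                                seed = derive_seed(config$seed,
                                                   pi * 1000L + ti))
        tip_seqs[[tips[ti]]] <- ev$cds
        tip_events[[tips[ti]]] <- ev$events
      }
    } else {
      node_seq <- list(); tip_seqs <- list(); tip_events <- list()
      ntips <- length(tips)
      root <- ntips + 1L
      node_seq[[root]] <- anc
      node_ev <- list()
      ord <- ape::reorder.phylo(tr, "cladewise")
      for (e in seq_len(nrow(ord$edge))) {
        par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
        bl <- ord$edge.length[e] * rate
        ev <- evolve_synonymous(node_seq[[par]], bl, prof,
                                config$bias_strength,
                                seed = derive_seed(config$seed,
                                                   pi * 100000L + e))
        node_seq[[child]] <- ev$cds
        node_ev[[child]] <- ev$events
        if (child <= ntips) {
          tip_seqs[[tips[child]]] <- ev$cds
          # cumulative events from root to tip
          path_ev <- list(); node <- child
          repeat {
            path_ev <- c(node_ev[node], path_ev)
            parent <- ord$edge[ord$edge[, 2L] == node, 1L]
            if (length(parent) == 0L) break
            node <- parent
          }
          tip_events[[tips[child]]] <- do.call(rbind, path_ev)
        }
      }
    }
    out[[pname]] <- unlist(tip_seqs)
    truth[[pname]] <- list(ancestor = anc, events = tip_events,
                           rate = rate)
  }
  structure(list(paralogs = out, truth = truth, config = config),
            class = "simulated_family")
}

#' Configuration for simulated gene neighborhoods
#'
#' Two "genomes" around one focal gene: planted orthologs (diverged at
#' synonymous sites, with optional nonsynonymous noise) among random decoys,
#' spaced so that both neighborhood caps are satisfiable.
#'
#' @param seed Integer seed.
#' @param n_orthologs Planted ortholog pairs.
#' @param n_decoys Unrelated decoy genes per genome.
#' @param gene_codons Codons per simulated gene (protein length).
#' @param spacing_bp Distance between consecutive gene starts.
#' @param syn_divergence Expected synonymous substitutions per synonymous
#'   site between ortholog copies.
#' @param nonsyn_rate Fraction of residues replaced in the genome-B ortholog
#'   copy (nonsynonymous noise).
#' @return List of class `neighborhood_config`.
#' @export
neighborhood_config <- function(seed = 1L, n_orthologs = 10L, n_decoys = 20L,
                                gene_codons = 100L, spacing_bp = 30000L,
                                syn_divergence = 0.1, nonsyn_rate = 0.05) {
  structure(list(seed = seed, n_orthologs = n_orthologs,
                 n_decoys = n_decoys, gene_codons = gene_codons,
                 spacing_bp = spacing_bp, syn_divergence = syn_divergence,
                 nonsyn_rate = nonsyn_rate),
            class = "neighborhood_config")
}

.random_protein <- function(n_aa) {
  aas <- setdiff(unique(.genetic_code()), "*")
  paste0(c("M", sample(aas, n_aa - 1L, replace = TRUE)), collapse = "")
}

.mutate_protein <- function(protein, rate) {
  aas <- strsplit(protein, "")[[1L]]
  all_aa <- setdiff(unique(.genetic_code()), "*")
  hit <- which(stats::runif(length(aas)) < rate)
  for (i in hit) aas[i] <- sample(setdiff(all_aa, aas[i]), 1L)
  paste0(aas, collapse = "")
}

#' Simulate two gene neighborhoods with planted orthologs
#'
#' @param config A [neighborhood_config()].
#' @return List of class `simulated_neighborhoods`: `genome_a`, `genome_b`
#'   (gene tables including the focal gene `focal`), `truth` (data.frame of
#'   planted ortholog pairs), `config`.
#' @export
simulate_neighborhoods <- function(config) {
  stopifnot(inherits(config, "neighborhood_config"))
  n_orth <- config$n_orthologs; n_dec <- config$n_decoys
  n_flank <- n_orth + n_dec

  genes_a <- vector("list", n_flank); genes_b <- vector("list", n_flank)
  pairs <- list()
  for (i in seq_len(n_flank)) {
    .with_seed(derive_seed(config$seed, 7000L + i), {
      if (i <= n_orth) {
        prot <- .random_protein(config$gene_codons)
        cds_a <- sample_gene(prot, bias_strength = 0)
        ev <- evolve_synonymous(cds_a, config$syn_divergence,
                                bias_strength = 0)
        prot_b <- .mutate_protein(translate_cds(ev$cds), config$nonsyn_rate)
        # re-encode mutated residues, keep synonymous choices elsewhere
        cods <- split_codons(ev$cds)
        aas_b <- strsplit(prot_b, "")[[1L]]
        tab <- .genetic_code()
        for (k in seq_along(cods)) {
          if (tab[[cods[k]]] != aas_b[k])
            cods[k] <- sample(synonymous_codons(aas_b[k]), 1L)
        }
        cds_b <- paste0(cods, collapse = "")
        ida <- sprintf("orthA_%02d", i); idb <- sprintf("orthB_%02d", i)
        pairs[[length(pairs) + 1L]] <- data.frame(genome_a = ida,
                                                  genome_b = idb)
        genes_a[[i]] <- list(id = ida, cds = cds_a)
        genes_b[[i]] <- list(id = idb, cds = cds_b)
      } else {
        cds_a <- sample_gene(.random_protein(config$gene_codons),
                             bias_strength = 0)
        cds_b <- sample_gene(.random_protein(config$gene_codons),
                             bias_strength = 0)
        genes_a[[i]] <- list(id = sprintf("decoyA_%02d", i), cds = cds_a)
        genes_b[[i]] <- list(id = sprintf("decoyB_%02d", i), cds = cds_b)
      }
    })
  }

  focal_prot <- .with_seed(derive_seed(config$seed, 1L),
                           .random_protein(config$gene_codons))
  focal_a <- sample_gene(focal_prot, bias_strength = 0,
                         seed = derive_seed(config$seed, 2L))
  focal_b <- evolve_synonymous(focal_a, config$syn_divergence,
                               bias_strength = 0,
                               seed = derive_seed(config$seed, 3L))$cds

  mk_genome <- function(genes, focal_cds, label, order_seed) {
    ids <- vapply(genes, `[[`, character(1), "id")
    cds <- vapply(genes, `[[`, character(1), "cds")
    ord <- .with_seed(order_seed, sample(length(ids)))
    ids <- ids[ord]; cds <- cds[ord]
    half <- length(ids) %/% 2L
    all_ids <- append(ids, "focal", after = half)
    all_cds <- append(cds, focal_cds, after = half)
    starts <- 1L + config$spacing_bp * (seq_along(all_ids) - 1L)
    data.frame(gene_id = all_ids, species = label, chrom = "chr1",
               start = starts,
               end = starts + 3L * config$gene_codons - 1L,
               strand = "+", cds = all_cds, stringsAsFactors = FALSE)
  }
  ga <- mk_genome(genes_a, focal_a, "genomeA", derive_seed(config$seed, 11L))
  gb <- mk_genome(genes_b, focal_b, "genomeB", derive_seed(config$seed, 12L))
  truth <- if (length(pairs) > 0L) do.call(rbind, pairs)
           else data.frame(genome_a = character(0), genome_b = character(0))
  structure(list(genome_a = ga, genome_b = gb, truth = truth,
                 config = config),
            class = "simulated_neighborhoods")
}

#' Random 3'UTR sequence
#'
#' @param length Sequence length.
#' @param gc GC content.
#' @param seed Optional seed.
#' @return Nucleotide string.
#' @export
random_utr <- function(length, gc = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Evolve a 3'UTR with substitutions and indels
#'
#' Per-site substitutions at `sub_rate` (always to a different base), then
#' `Poisson(indel_rate * length)` indel events at random positions with
#' geometric lengths (mean `mean_indel_len`), insertions and deletions
#' equally likely. All edits are recorded.
#'
#' @param utr Nonempty nucleotide string.
#' @param sub_rate Per-site substitution probability.
#' @param indel_rate Expected indels per site.
#' @param mean_indel_len Mean indel length (>= 1).
#' @param seed Optional seed.
#' @return List: `utr` (evolved), `n_substitutions`, `indels` (data.frame
#'   type/position/length).
#' @export
evolve_utr <- function(utr, sub_rate = 0.1, indel_rate = 0.01,
                       mean_indel_len = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!nzchar(utr)) stop("empty UTR")
  bases <- strsplit(toupper(utr), "")[[1L]]
  hit <- which(stats::runif(length(bases)) < sub_rate)
  for (i in hit) bases[i] <- sample(setdiff(BASES, bases[i]), 1L)
  n_indels <- stats::rpois(1L, indel_rate * length(bases))
  indels <- data.frame(type = character(0), position = integer(0),
                       length = integer(0))
  if (n_indels > 0L) {
    for (k in seq_len(n_indels)) {
      len <- 1L + stats::rgeom(1L, 1 / mean_indel_len)
      pos <- sample.int(length(bases), 1L)
      if (stats::runif(1L) < 0.5) {       # insertion after pos
        ins <- sample(BASES, len, replace = TRUE)
        bases <- append(bases, ins, after = pos)
        indels <- rbind(indels, data.frame(type = "ins", position = pos,
                                           length = len))
      } else {                            # deletion starting at pos
        del_to <- min(length(bases), pos + len - 1L)
        bases <- bases[-(pos:del_to)]
        indels <- rbind(indels, data.frame(type = "del", position = pos,
                                           length = del_to - pos + 1L))
        if (length(bases) == 0L) break
      }
    }
  }
  list(utr = paste0(bases, collapse = ""),
       n_substitutions = length(hit), indels = indels)
}

#' Write a simulated family to FASTA files plus a JSON truth file
#'
#' @param fam A `simulated_family`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_family <- function(fam, dir) {
  stopifnot(inherits(fam, "simulated_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (pname in names(fam$paralogs)) {
    p <- file.path(dir, paste0(pname, ".fasta"))
    write_fasta(fam$paralogs[[pname]], p)
    paths <- c(paths, p)
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- lapply(fam$truth, function(t)
    list(ancestor = t$ancestor, rate = t$rate,
         events = lapply(t$events, function(e) as.list(e))))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, truth_path))
}
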