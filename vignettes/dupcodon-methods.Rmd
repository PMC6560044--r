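---
title: "Methods: measuring selection and codon usage in duplicate genes with an identical protein product"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring selection and codon usage in duplicate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupcodon)
```

## The problem

Several vertebrate genes exist in duplicate copies that encode *exactly the
same protein* — the motivating case is the replication-independent histone
variant H3.3, encoded twice in essentially all tetrapod genomes. Because
the protein is invariant, the usual machinery for measuring selection
(ratios of nonsynonymous to synonymous substitution rates) has nothing to
work with: all between-copy and between-species coding differences are
synonymous. Yet the two copies are clearly not equivalent — they differ in
regulation, in codon usage, and in how strongly their *synonymous* sites
are conserved. `dupcodon` quantifies those differences directly at the
nucleotide level.

## Substitution scores and conserved sites

Two CDSs that encode the same protein align codon-for-codon without gaps,
so the **nucleotide substitution score** is simply the number of mismatching
positions divided by the CDS length — a raw, model-free genetic distance.
We deliberately apply no multiple-hit correction: the analysis compares
*distributions* of scores between genes (by Mann–Whitney rank-sum tests),
and a monotone transform would not change those comparisons. When CDSs of
unequal length are supplied, the denominator defaults to the number of
gap-free codon-alignment columns, which reduces to the CDS length in the
identical-protein case; the shorter or mean CDS length can be chosen
instead.

For a group of organisms we classify each gap-free codon column of the
alignment by third-position degeneracy under the standard genetic code:

- a **wobble site** has fold ≥ 2 in every row (a synonymous change is
  possible everywhere);
- a **fourfold degenerate site** has fold 4 in every row (*any* nucleotide
  substitution is synonymous, so the site is free of protein-level
  constraint).

Requiring the degeneracy class to hold in *every* row is automatic when the
protein is identical, and is the only defensible reading of "a site where
any substitution is synonymous" when it is not. Stop codons are excluded
from all site counts and from GC3. A site is **absolutely conserved** when
all organisms of the group carry the same nucleotide; the report gives
conserved count, total and frequency, and `freq_ratio()` forms the
between-paralog ratio of those frequencies. A ratio above 1 means the first
gene retains more absolutely conserved synonymous sites — purifying
selection acting below the protein level. The ratio grows with the
divergence depth of the group (deeper groups have had more time to strip
unconstrained sites in the weakly constrained copy), and at sufficient
depth the denominator can reach zero, in which case the ratio is reported
as undefined rather than truncated or imputed.

The Mann–Whitney test switches between the exact distribution (smaller
group ≤ 8 and no ties) and the tie-corrected normal approximation with
continuity correction. The switch point gives reproducible exact p-values
at the group sizes typical of these comparisons; the large-sample branch is
calibrated (simulated type-I error ≈ 0.05 at α = 0.05; checked in the test
suite at 10,000 null replicates).

## Alignment and the gap-excluded identity

All pairwise alignments use an internal Needleman–Wunsch with affine gap
penalties (Gotoh's algorithm, compiled via Rcpp). A gap of length *k*
scores `gap_open + k * gap_extend`; nucleotide defaults are match +2,
mismatch −1, gap_open −5, gap_extend −1, and protein alignments use BLOSUM62
with gap_open −10, gap_extend −1. Traceback ties are broken in a fixed
order (diagonal, then gap in the second sequence, then gap in the first;
gap opening preferred over extension), so alignments are bit-reproducible
across platforms. The test suite verifies optimality against exhaustive
alignment enumeration on short sequences and against an independent
implementation on longer ones.

Sequence identity is always reported **gap-excluded**:
`identity = 1 − M/N`, where `N` counts only columns in which neither
sequence has a gap and `M` the mismatches among them. Insertions and
deletions therefore contribute nothing to the score — essential for 3′UTRs,
whose indel-rich evolution would otherwise drown the substitution signal.
When no gap-free column exists the identity is an error, not zero. One
subtlety: the identity is computed on the *optimal* alignment, which near
dense indels may absorb an occasional mismatch into a longer gap, so an
indel-only divergence scenario yields identity ≈ 1 rather than exactly 1 in
rare configurations.

Codon-aware multiple alignment backs protein-level alignment down to
nucleotides, so gaps occur only in whole-codon triplets and every column
keeps its codon-position meaning. With identical proteins (the case this
package exists for) the alignment is exact column stacking; otherwise a
star progressive alignment around the longest protein is used — adequate
for the near-identical proteins met here, and not intended as a general
MSA engine.

## Codon-usage metrics and benchmarking

Two metrics are provided. **Raw codon frequencies** divide each codon's
occurrences by the gene's total codon count. **Amino-acid-specific
frequencies** divide by the count of the encoding amino acid, giving the
conditional probability of the codon given its amino acid; this removes
amino-acid-composition effects and is the metric used for all program
benchmarking. Codons of an amino acid absent from a gene are *undefined*
under the conditional metric — they are dropped pairwise from correlations,
never imputed as zero, because a conditional probability with an empty
condition has no value and zero-imputation systematically distorts r for
short genes. Under the conditional metric the single-codon amino acids
(Met, Trp) are excluded from correlation vectors by default: their
frequency is the constant 1 and only inflates r. Both choices are
configurable, and every correlation reports the number of codon dimensions
used so the filter is auditable.

Group profiles pool codon counts across genes before normalizing (a
length-robust choice; a per-gene-mean variant exists as an option). When a
benchmarked gene belongs to the gene set it is compared against, it is left
out of that set's pooled profile by default to avoid self-correlation bias.
Program assignment is by the larger correlation against the two program
profiles, with the gene's rank percentile within each program's own-gene
benchmark distribution reported alongside.

Genome-wide codon counts are read from Kazusa-style codon usage tables
(codon, per-mille, count triplets; RNA or DNA spelling), and the writer
round-trips bit-exactly.

## The synteny scan

The neighborhood of a focal gene is the set of up to 30 genes per side
lying within ±1.5 Mb of its span — both caps apply simultaneously, which is
the conservative reading of "either 30 genes or the maximal number within
the window". Strand affects only the upstream/downstream labels, not
membership: the scan compares unordered gene sets, not collinearity. Every
query flanking gene is scored by its *maximal* CDS identity and maximal
protein identity (gap-excluded) over all reference genes, so enlarging the
reference (pooling neighborhoods across species, de-duplicated by gene id)
can only raise scores — the property that makes pooled references a
sensitivity tool. A gene is called syntenic when protein identity ≥ 0.40
with at least 50 % of the shorter protein in gap-free columns *and* CDS
identity ≥ 0.50. These thresholds separate the simulated ortholog regime
(≤ 20 % synonymous + ≤ 10 % nonsynonymous divergence: identities ≥ 0.8)
from the random-decoy regime (protein identity ~ 0.2–0.35 even after
maximizing over 30 references; CDS identity alone is *not* discriminative —
optimal alignment of unrelated CDSs yields ~ 0.55, which is why the call
requires the protein condition). All thresholds are echoed into output
metadata.

## The synthetic-data generator

No accessions are distributed with the analysis this package implements,
so all testing runs on generated data with planted truth. The generator
emulates:

- **Ortholog panels of an identical-protein family.** A fixed synthetic
  136-residue protein of realistic amino-acid composition (the length of
  the motivating histone variant; deliberately *not* a database sequence)
  is encoded by sampling each codon from a mixture
  `bias · target-profile + (1 − bias) · uniform-over-synonyms`, then evolved
  along a star or user-supplied newick tree. Substitutions operate in codon
  space — an event resamples one codon among its synonyms — which guarantees
  protein invariance by construction, at the cost of not modelling
  transition/transversion or CpG effects (a stated limitation, acceptable
  because the downstream statistics count *any* synonymous change). The
  event count per branch is Poisson with mean `branch length × number of
  codons with ≥ 2 synonyms`. Two paralogs differ by rate multipliers,
  default 1 vs 5 with a tip branch length of 0.05 expected synonymous
  substitutions per site — a within-clade level of divergence at which both
  copies retain signal; the nested-depth tree used in the analysis scripts
  adds tips at 0.01/0.08/0.3 to emulate shallow, intermediate and deep
  organism groups.
- **Program gene sets** drawn from amino-acid-specific target profiles that
  prefer G/C-ending or A/T-ending codons (weight 4:1 within each synonym
  family; Jensen–Shannon divergence ≈ 0.28 between the two targets), and a
  "genome-wide" background pooled from the mixture of both.
- **Gene neighborhoods** with a focal gene, planted orthologs (synonymous
  divergence plus a small nonsynonymous admixture) and unrelated random
  decoys, at 30 kb spacing so both neighborhood caps are satisfiable.
- **3′UTRs** evolved with per-site substitutions and geometric-length
  indels, every edit recorded.

Every generator records its planted truth (ancestors, per-branch event
lists, ortholog pairings) in replayable form; the suite asserts that
replaying the events reproduces each emitted sequence byte-for-byte, and
that identical seeds give identical output files. Per-gene RNG substreams
are derived from the run seed, so outputs do not depend on iteration
order.

What passing on these data does **not** show: robustness to real mutation
spectra (ts/tv, CpG hotspots), to annotation errors, to paralog
misassignment, or to the acquisition biases of real genome databases. The
generator's orthologs are honestly diverged but structurally clean —
equal-length CDSs, no splice-form ambiguity, no missing data.

## Problem sizes and numerical choices

The recovery analyses in the test suite use 200 seeded replicates each
(two-paralog families on 8-tip star trees; 200 + 200 program genes of 136
codons; neighborhoods of 10 planted orthologs among 20 decoys), and the
acceptance script reruns the same computations at 50/100/25 replicates —
sizes chosen to estimate the recovery rates to a few percent while keeping
a full rerun in the minutes range. Exact rank-sum p-values are verified
against full permutation enumeration for group sizes ≤ 7; alignment
optimality against exhaustive enumeration over all short sequence pairs
(every pair up to length 2, plus a seeded sample of lengths 3–5, where the
enumeration grows combinatorially). Degenerate inputs are surfaced, never
silently defaulted: undefined identity (no gap-free columns), undefined
conserved-site frequency (no sites of the class), undefined frequency
ratio (zero denominator) and ambiguous program assignment (identical
profiles) are all explicit states.

## Known limitations

- The codon-space substitution model cannot generate the mutational
  asymmetries that shape real synonymous-site evolution; rate *contrasts*
  between paralogs are faithful, absolute rates are nominal.
- The star progressive aligner is not a general MSA tool; it is exact for
  the identical-protein case and adequate for near-identical proteins.
- Synteny thresholds were set to separate the simulated regimes; against
  real annotations, where gene structures and lengths vary far more, they
  should be treated as tunable starting points (they are parameters, and
  every output records them).
- The conserved-site frequency ratio saturates (denominator → 0) once the
  fast-evolving copy loses all absolutely conserved sites of a class; at
  that point only the one-sided statement "deeper than measurable" remains.
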