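---
title: "Annotating and analysing chemosensory receptor repertoires"
author: "chemoreceptR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and analysing chemosensory receptor repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures `chemoreceptR`
implements, the parameters that matter, the design choices made where
the design was genuinely open, and what the synthetic-data tests do and
do not establish about real data.

## The problem

Insect odorant (*Or*), gustatory (*Gr*) and variant ionotropic (*Ir*)
receptor genes evolve by rapid birth-and-death: tandem duplication
builds large same-family arrays, and many copies decay into pseudogenes.
In a draft genome two mechanisms produce fragmentary gene models:
genuine pseudogenisation (frameshifts, premature stop codons) and
truncation by assembly artefacts (scaffold edges, runs of N). Off-the-
shelf annotation underestimates such repertoires badly, so the field
uses dedicated homology pipelines followed by evolutionary
(reconciliation, birth–death) and transcriptomic (FPKM, sex-enrichment)
analyses. This package provides that whole chain as tested code, with
simulators that plant known truth so each stage can be scored.

## The annotation pipeline

One round runs: search → filter → chain → merge → predict → length
filter. Rounds iterate with the previous round's predictions added to
the query set, until the locus set stabilises.

**Search.** Hits can be read from 12/13-column tabular files, or
generated by the built-in translated search: the six frame translations
of the genome are indexed by exact amino-acid 6-mers; seed clusters
define windows; each window is aligned to the query by an affine-gap
Smith–Waterman kernel (BLOSUM62, gap open 12, extend 1) whose traceback
is X-drop-trimmed — each tail is cut back to its last score peak once
the running score drops more than 12 below it, and the best-scoring
segment is kept. Without this, optimal local alignments routinely carry
weakly positive read-through across exon/intron boundaries. One window
may yield several HSPs (short introns, disrupted exons); the unmatched
flanks are re-aligned recursively. Raw scores map to bit scores with the
usual gapped BLOSUM62 Karlin–Altschul constants. The search is a
deliberately simple stand-in: it assumes the target genes resemble some
query at roughly ≥ 70% amino-acid identity over 6-mer-bearing stretches,
which is the regime the iterative design addresses (divergent paralogs
are reached through intermediate predictions, not in one hop).

**Filter.** Hits with e-value above `1e-5` are dropped; then hits
scoring below 25% of the mean bit-score of the top
`ceil(0.75 · N)` hits are dropped. The average is computed over the
whole search run by default; a per-query mode is available
(`score_filter_scope`), since either reading of "the top 75% of HSPs"
is defensible.

**Chain.** Within each (query, scaffold, strand) group, hits are sorted
in transcription order and consecutive hits are linked when the
nucleotide gap is at most 3 kb *and* the upstream hit is strictly
N-terminal on the query. The second criterion is what stops two
neighbouring paralogs — whose exons also lie within 3 kb — from being
concatenated: a fresh paralog restarts near the query N-terminus.
"Upstream" is defined in transcription order; on the minus strand the
criterion would otherwise be meaningless.

**Merge.** Chains whose genomic extents overlap on the same strand
become one locus; adjacent but disjoint chains stay separate (the 3-kb
rule already absorbs within-gene gaps, and merging disjoint regions
would reintroduce the concatenation artefact). The locus's reference
query is the one holding the maximum bit-score hit, ties broken
lexicographically. A 2-kb flank (`region_flank_nt`) is added before
prediction — large enough for terminal-exon extension, configurable.

**Predict (HSP stitcher).** The reference query's hits become exons:
query overlaps between consecutive segments are split at the midpoint in
whole codons; exon/intron junctions are then refined against the query —
candidate shifts of up to 25 codons per side must produce canonical
GT…AG intron ends, and the candidate whose translated junction context
(8 residues each side, BLOSUM62) best explains the query wins, but only
if it beats the current boundary. Terminal exons extend to the nearest
in-frame start/stop within the flank, and the terminal exon is cut at
its first in-frame stop so 3' read-through never looks like a premature
stop. Disruptions are recorded rather than fatal: in-exon stops,
frame-inconsistent near-adjacent breaks (gap below `min_intron_nt = 40`
and not a codon multiple), stops hidden in small in-frame gaps the
aligner skipped, and three junction-level signals for disruptions
absorbed into apparent introns — an imbalanced junction (query support
strong on one flank, at chance on the other, with a query-coverage
jump), a flank at or below zero support with contiguous coverage (an
indel at the boundary), and a boundary repairable only by a 1–2 nt
off-grid shift. Before an imbalanced junction is called disrupted, the
missing query segment is searched in the junction DNA: a high-identity,
stop-free hit means a merely *missed* clean exon, not a disruption.
Disruption evidence accumulates across pipeline rounds, because a later
round's reference query may be a clean prediction that no longer spans
the broken piece.

**Length filter.** Predictions are sorted by ORF length (the longest
disruption-free stretch) and the lowest quartile removed, per family and
per round — families differ in typical length, and pooling would bias
against short families. The unfiltered final-round set is also returned
(`models_unfiltered`) for repertoire-wide statistics, since fragment
models are part of the annotation even when they are not recycled as
queries.

**Convergence.** Locus sets are compared between rounds by reciprocal
extent overlap of at least 50% of the shorter locus, so prediction
jitter cannot prevent termination; `max_iterations = 10` caps the loop
with a warning.

## Classification

Decision order: (1) ORF ≥ `min_intact_aa` (300 aa; the cutoff is
configurable because shorter cutoffs are conventional for other
species) with zero disruptions → `intact`, with IR models additionally
passing a pluggable domain check (the shipped default is a pass-through;
an external domain scanner can be plugged in); (2) any disruption →
`pseudogene` — one verified disruption already breaks the ORF, and the
count is kept so stricter thresholds can be applied; (3) short and
within `edge_distance_nt = 5 kb` of a scaffold end or an N-run ≥ 100 nt
→ `partial_assembly` (the 5-kb proximity is an assumption, exposed as a
parameter); (4) otherwise `short_unresolved`. `classify_model`
re-derives disruption counts from the genome but keeps
predictor-recorded evidence (the junction-level signals above) that a
pure re-derivation cannot see.

## Tandem clusters

Per scaffold and family, maximal runs of genes with start-to-start gaps
≤ `cluster_gap_nt = 20 kb`; strand is ignored (arrays contain
inversions) and intervening genes of other families do not break a run.
No threshold is standard in the literature; 20 kb recovers the planted
arrays exactly and is configurable. Runs of size one are singletons, not
clusters.

## Family evolution

**Support collapsing** contracts internal edges with bootstrap support
strictly below 70 (missing supports are treated as below any threshold —
conservative for orthology claims), accruing contracted branch lengths
to children.

**Reconciliation** maps each gene-tree node to the LCA of its
descendants' species; a node mapping onto a child's map is a
duplication; losses are attributed branch-by-branch along the species
path each lineage descends. The family is taken to be present (single
copy) at the species-tree root, so missing lineages imply stem losses.
Polytomies are resolved into the binary refinement minimising
duplications + losses — exhaustively up to 7 children (10,395
topologies), greedily above, and the local minimisation is globally
valid because a polytomy's LCA map does not depend on its resolution.
Ancestral copy numbers follow from the per-branch gains and losses.

**Birth–death model.** Family sizes evolve by a per-copy linear
birth–death process; with birth = death = λ the single-copy offspring
distribution has extinction and geometric parameters
`p0 = eta = λt/(1+λt)`, and the i-copy transition is the convolution
given in the README. The rate is fitted by Felsenstein pruning over
copy-number states, maximising the product over families of
*root-integrated* likelihoods (uniform weight over root counts
1…2·max). The design here was genuinely open: profiling one free root
count per family — the empirical-Bayes maximisation that first seemed
natural — has an incidental-parameters bias that underestimates λ by
roughly 20% *independently of the number of families*, because each
family's root chases its own leaf counts. Integration removes the bias
(recovery within a few percent at 500 families) while per-family root
and ancestral estimates are still reported as conditional maximisers
(max-product assignments), which is what a per-branch gain/loss table
needs. A two-rate (birth ≠ death) fit is available behind
`equal_rates = FALSE`. State space is truncated at `2·max(count) + 5`;
transition rows then sum to one within 10⁻⁹ for λt ≤ 1.

**Violation test.** A parametric bootstrap: simulate null families at
the fitted rate (root sizes resampled from the fitted roots), score
every family by its profiled log-likelihood, and report the
tie-randomised rank of each observed family among the simulations.
Randomised ranks make the p-values exactly uniform under the null
despite the discreteness of count data; lineage-specific expansions land
in the lower tail.

**Count parsimony** (Sankoff, unit cost per copy) provides the
conservative counterpart: the minimal number of gain/loss events able to
explain the leaf counts, which can never exceed the true simulated event
count, and which posits smaller ancestral repertoires than the
likelihood fit when losses are frequent — the qualitative contrast the
two estimators are known for.

## Expression

FPKM is `count · 10⁹ / (total_fragments · exon_length)`. A gene is
*expressed* in a sample iff its FPKM is strictly above the median of
that sample's whole transcriptome — supply the full table, not only the
receptors. Sex enrichment is the pure fold-change rule
`(a + ε)/(b + ε) ≥ 2` with pseudocount ε = 0.1 FPKM (the published
analyses applied the two-fold rule on FPKM; whether a pseudocount was
used is not stated, so ε is exposed); a pluggable significance gate can
veto calls, and a simple conditional-binomial stand-in is provided —
clearly not a reimplementation of any external DE engine, and off by
default. Orthogroups are the *smallest* clades with support ≥ 70
containing both species: smallest clades maximise resolution and make
groups disjoint. A group is classifiable iff each species contributes a
non-null labelled gene; within-species disagreement makes it
`conflicting`, otherwise the species directions give `same_sex` or
`different_sex`, and the three classes partition the classifiable groups
by construction.

## What the simulators emulate — and what they do not

`simulate_genome` plants multi-exon genes (3/5/7/9 exons; nine-exon
architectures are the hallmark of the largest ant *Or* subfamily) in
per-family tandem arrays, with defaults chosen once to mirror the
published genomic organisation: ~75% of *Or* genes in arrays of ≥ 4, and
half the *Gr* genes with at least one neighbour (pairs). Pseudogenes
carry two disruptions placed uniformly after codon 30 (keeping fragments
detectable by homology), the first before codon 280, and are re-drawn
until the disruption is visible in the spliced translation — an
undetectable "pseudogene" would be a contradiction in terms for a
planted truth set. Edge fragments keep about half their exons and stop
at a scaffold end or a 300-nt N-run, with the kept coding capped below
an intact-length ORF. Introns are phase-0 GT…AG of 200–800 nt; genes
derive from per-family ancestor proteins by 10% point substitution.

Deliberate simplifications: no phase-1/2 introns, no alternative codon
usage, no repeats or segmental duplications, substitution-only
divergence (no indels between paralogs), and uniform intergenic
composition. Passing the recovery tests therefore shows the pipeline's
logic is correct under realistic gene architecture — not that it matches
a hand-curated annotation of a real draft genome, where alignment gaps,
repeats and assembly chimeras add failure modes this generator does not
model.

`simulate_family_history` is an exact Gillespie simulation of the
per-copy birth–death process, recording per-branch event counts — so
likelihood and parsimony estimators can be scored against events, not
just leaf counts. `simulate_counts` draws negative-binomial counts; the
default dispersion 0.05 represents replicate-level antennal libraries
(whole-transcriptome concordance near r² = 0.99 between worker
samples), while the harder cross-individual setting 0.3 is used where
the concordance-recovery checks prescribe it. Planted sex-enrichment
effects are eight-fold, matching the reported scale (log₂ fold-changes
above 3 for worker/male differences); planted genes sit inside a
300-gene stable transcriptome so that FPKM's compositional normalisation
is realistic.

## Numerical choices and problem sizes

* Alignment: BLOSUM62, gap open 12 / extend 1, X-drop 12, seed k = 6,
  window pad 10 aa; Karlin–Altschul λ = 0.267, K = 0.041.
* Junction refinement: ±25 codons, context window 8 aa, a candidate must
  beat the incumbent by > 2; ties prefer the smaller shift.
* Reconciliation oracle testing is exhaustive over every labelled
  binary gene-tree topology with 2–4 leaves on a 4-taxon species tree,
  plus 400 seeded random 5–6-leaf trees; the package's LCA result
  agrees with the brute-force minimum on all of them. Full exhaustion
  at 6 leaves (tens of thousands of canonical trees) adds no
  qualitative coverage.
* Birth–death checks: 500 families for rate recovery on a six-taxon,
  ~250-My-deep tree at λ = 0.002; 10⁶ Gillespie replicates for the
  transition-probability check; 600 bootstrap replicates for the
  calibration test.
* The flagship annotation fixture is 12 scaffolds × 300 kb with 85
  planted genes (60 intact, 15 pseudogenes, 10 edge fragments) — small
  enough to run in about a minute, large enough to contain every
  planted failure mode.

## Known limitations

* The built-in search needs an exact amino-acid 6-mer shared with some
  query; genes below ~70% identity to every query (and every
  intermediate prediction) stay invisible.
* A disruption confined to the last exon's final codons can escape
  detection, and a frameshift absorbed exactly at an exon boundary is
  only caught through the off-grid-repair heuristic; both directions of
  error (a rare false pseudogene call on an intact gene, and vice
  versa) occur at the few-percent level on the flagship fixture.
* Reconciliation assumes the family is present at the species-tree
  root and does not model horizontal transfer.
* The birth–death fit assumes a single rate shared across families and
  branches; the violation test exists precisely to flag families that
  break it.
* Expression analysis consumes counts; read mapping, fragment counting
  and bias correction are out of scope.
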