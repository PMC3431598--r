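# chemoreceptR

Insect chemosensory receptor repertoires — odorant receptors (*Or*),
gustatory receptors (*Gr*) and variant ionotropic receptors (*Ir*) — are
among the largest and fastest-evolving gene families in animal genomes.
In draft assemblies of social insects such as ants, hundreds of receptor
loci hide in tandem arrays, many of them pseudogenised or cut by contig
edges, and standard automated annotation recovers only a fraction of
them. `chemoreceptR` implements, as tested reusable R code, the
homology-based annotation pipeline used to chart such repertoires and
the downstream evolutionary and transcriptomic analyses that depend on
it:

* **Annotation** — TBLASTN-style hits (ingested from tabular files, or
  produced by the built-in seed-and-extend translated search with a
  Smith–Waterman kernel) are filtered at e ≤ 10⁻⁵ and at 25% of the mean
  bit-score of the top 75% of hits; hits are chained when they come from
  the same query, lie within 3 kb on the same strand, and are collinear
  on the query (the criterion that prevents neighbouring paralogs from
  being fused); chained regions become loci, a reference query is chosen
  by best bit-score, a gene model is stitched from the HSPs with
  GT…AG-aware junction refinement, the lowest ORF-length quartile is
  dropped per family, and the surviving predictions are fed back as
  queries until no new loci appear.
* **Classification** — models become `intact` (ORF ≥ 300 aa, no
  disruption; IR models additionally pass a pluggable domain check),
  `pseudogene` (frameshifts / premature stops, including disruptions
  hidden behind spurious "introns"), `partial_assembly` (short, clean,
  within 5 kb of a scaffold end or an N-run ≥ 100 nt) or
  `short_unresolved`.
* **Tandem clusters** — per family and scaffold, maximal runs of genes
  with start-to-start gaps ≤ 20 kb.
* **Family evolution** — bootstrap-aware collapsing of gene-tree
  branches below support 70; duplication–loss reconciliation against a
  species tree by LCA mapping with exhaustive polytomy resolution
  (≤ 7 children); single-copy ortholog clade detection;
  maximum-likelihood birth–death modelling of family sizes
  (`P(i→j) = Σₖ C(i,k) p₀^(i−k) (1−p₀)^k C(j−1,k−1) (1−η)^k η^(j−k)`,
  with `p₀ = η = λt/(1+λt)` for birth = death) with ancestral copy
  numbers and a parametric-bootstrap test of the birth–death assumption;
  minimum-change count parsimony as the conservative counterpart.
* **Expression** — FPKM (`count · 10⁹ / (total · length)`), the
  median-of-transcriptome expression criterion, two-fold worker/male
  enrichment with a pluggable significance gate, smallest supported
  two-species orthogroups, and same-sex / different-sex / conflicting
  concordance classes.
* **Simulators** — genomes with planted multi-exon receptor genes
  (including nine-exon architectures) in tandem arrays, pseudogenes and
  edge-truncated fragments; gene-family histories under a per-copy
  birth–death process with full event logs; negative-binomial count
  matrices with planted sex enrichment. Every downstream claim in the
  test suite is scored against this ground truth.

## Worked example

```r
library(chemoreceptR)

sim <- simulate_genome(genome_sim_spec(seed = 42))   # 12 x 300 kb, 85 genes
res <- run_iterative_pipeline(sim$genome, sim$queries,
                              family = list(OR = "^OR", GR = "^GR"))
res$log
#>    round n_queries n_hsps n_loci n_models
#> 1:     1         6    658     85       64
#> 2:     2        70   7298     85       64

models <- lapply(res$models, classify_model, genome = sim$genome)
fragment_mechanism_report(models)[family == "all",
                                  .(n, intact, pseudogene, partial_assembly)]
#>        n intact pseudogene partial_assembly
#> 1:    64     56          8                0

st <- cluster_statistics(find_clusters(res$models_unfiltered),
                         family = "OR", min_report_size = 4)
round(100 * st$frac_in_big_clusters)
#> [1] 75
```

The run discovers all 85 planted loci in round 1, adds nothing in round
2 and stops; the per-family ORF-length filter leaves 64 reported models.
75% of the odorant-receptor models sit in tandem arrays of four or more
genes — the genomic organisation the simulator plants, and the one
reported for real ant *Or* repertoires.

Downstream, the same objects feed the evolutionary layer:

```r
tr  <- read_tree(text = "(((A:50,B:50):100,(C:70,D:70):80):100,(E:120,F:120):130);")
h   <- simulate_family_history(tr, 0.002, 0.002, root_size = 25,
                               n_families = 500, seed = 11)
fit <- fit_birth_death(h$counts, tr)
round(fit$lambda, 5)
#> [1] 0.00194
```

a per-copy rate within a few percent of the simulating value 0.002.

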