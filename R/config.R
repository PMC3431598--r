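#' Pipeline configuration
#'
#' Collects every numeric parameter used across the annotation and analysis
#' stages in one validated object. The defaults are the protocol the
#' pipeline implements: TBLASTN-style hits are kept at e-value <= 1e-5, the
#' bit-score gate is 25% of the mean of the top 75% of hits, HSPs are chained
#' within 3 kb on the same strand, the lowest length-quartile of predictions
#' is dropped each round, intact Or/Gr models must reach 300 aa, gene-tree
#' branches below bootstrap 70 are collapsed, and two-fold change defines
#' sex enrichment.
#'
#' @param evalue_cutoff maximum e-value for a retained HSP.
#' @param top_fraction fraction of top-scoring HSPs whose mean bit-score
#'   anchors the score filter (in (0, 1]).
#' @param score_fraction minimum bit-score as a fraction of that mean.
#' @param chain_gap_nt maximum nucleotide gap between chained HSPs.
#' @param orf_filter_fraction fraction of shortest-ORF predictions removed
#'   per family per round.
#' @param min_intact_aa minimum ORF length (aa) for an intact model.
#' @param region_flank_nt flank added around a locus before gene prediction.
#' @param edge_distance_nt maximum distance from a scaffold end or N-run for
#'   the assembly-truncation call.
#' @param collapse_support bootstrap threshold: branches with support
#'   strictly below it are collapsed.
#' @param expression_fold fold-change defining sex enrichment.
#' @param cluster_gap_nt maximum start-to-start gap between tandem-cluster
#'   neighbours.
#' @param cluster_min_size minimum cluster size reported by the headline
#'   cluster statistics.
#' @param max_iterations cap on annotation pipeline rounds.
#' @param score_filter_scope `"global"` (one bit-score average per search
#'   run) or `"per_query"`.
#' @param min_intron_nt gaps below this within a chain are treated as breaks
#'   inside one exon (candidate frameshifts), not introns.
#' @param pseudocount_fpkm pseudocount (FPKM units) used in fold-change
#'   ratios.
#' @param rng_seed integer seed recorded for simulation-driven steps.
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$chain_gap_nt
#' @export
pipeline_config <- function(evalue_cutoff = 1e-5,
                            top_fraction = 0.75,
                            score_fraction = 0.25,
                            chain_gap_nt = 3000L,
                            orf_filter_fraction = 0.25,
                            min_intact_aa = 300L,
                            region_flank_nt = 2000L,
                            edge_distance_nt = 5000L,
                            collapse_support = 70L,
                            expression_fold = 2.0,
                            cluster_gap_nt = 20000L,
                            cluster_min_size = 4L,
                            max_iterations = 10L,
                            score_filter_scope = c("global", "per_query"),
                            min_intron_nt = 40L,
                            pseudocount_fpkm = 0.1,
                            rng_seed = 1L) {
  score_filter_scope <- match.arg(score_filter_scope)
  cfg <- list(
    evalue_cutoff = as.numeric(evalue_cutoff),
    top_fraction = as.numeric(top_fraction),
    score_fraction = as.numeric(score_fraction),
    chain_gap_nt = as.integer(chain_gap_nt),
    orf_filter_fraction = as.numeric(orf_filter_fraction),
    min_intact_aa = as.integer(min_intact_aa),
    region_flank_nt = as.integer(region_flank_nt),
    edge_distance_nt = as.integer(edge_distance_nt),
    collapse_support = as.integer(collapse_support),
    expression_fold = as.numeric(expression_fold),
    cluster_gap_nt = as.integer(cluster_gap_nt),
    cluster_min_size = as.integer(cluster_min_size),
    max_iterations = as.integer(max_iterations),
    score_filter_scope = score_filter_scope,
    min_intron_nt = as.integer(min_intron_nt),
    pseudocount_fpkm = as.numeric(pseudocount_fpkm),
    rng_seed = as.integer(rng_seed)
  )
  for (fr in c("top_fraction", "score_fraction", "orf_filter_fraction")) {
    if (!is.finite(cfg[[fr]]) || cfg[[fr]] <= 0 || cfg[[fr]] > 1) {
      stop(sprintf("'%s' must lie in (0, 1]", fr), call. = FALSE)
    }
  }
  for (d in c("chain_gap_nt", "region_flank_nt", "edge_distance_nt",
              "cluster_gap_nt", "min_intron_nt")) {
    if (is.na(cfg[[d]]) || cfg[[d]] <= 0) {
      stop(sprintf("'%s' must be a positive distance", d), call. = FALSE)
    }
  }
  if (cfg$evalue_cutoff <= 0) stop("'evalue_cutoff' must be positive", call. = FALSE)
  if (cfg$max_iterations < 1L) stop("'max_iterations' must be >= 1", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Internal: run a block with a private, restored RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
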