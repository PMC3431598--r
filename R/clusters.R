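#' Detect tandemly arrayed gene clusters
#'
#' Per scaffold and family, genes are sorted by start coordinate and
#' maximal runs whose consecutive start-to-start gaps are at most
#' `cluster_gap_nt` form a cluster. Strand is ignored (tandem arrays
#' commonly contain inversions) and intervening genes of other families do
#' not break a run. Runs of size 1 are reported as singletons, not
#' clusters.
#'
#' @param models list of [gene_model()] objects (or a table from
#'   [models_to_table()]).
#' @param config a [pipeline_config()].
#' @return A list with `clusters` (a `data.table`: `cluster_id`,
#'   `scaffold_id`, `family`, `span_start`, `span_end`, `size`, comma-join
#'   of member ids) and `genes` (per-gene table with `cluster_id`, `NA`
#'   for singletons).
#' @export
find_clusters <- function(models, config = pipeline_config()) {
  tab <- if (is.data.frame(models)) data.table::as.data.table(models)
         else models_to_table(models)
  if (nrow(tab) == 0L) {
    return(list(clusters = data.table::data.table(
      cluster_id = integer(), scaffold_id = character(), family = character(),
      span_start = integer(), span_end = integer(), size = integer(),
      members = character()), genes = tab))
  }
  tab <- data.table::copy(tab)
  tab$cluster_id <- NA_integer_
  cid <- 0L
  for (key in unique(paste(tab$scaffold_id, tab$family))) {
    ix <- which(paste(tab$scaffold_id, tab$family) == key)
    ix <- ix[order(tab$start[ix])]
    run <- list(ix[1])
    if (length(ix) > 1L) {
      for (k in 2:length(ix)) {
        gap <- tab$start[ix[k]] - tab$start[ix[k - 1L]]
        if (gap <= config$cluster_gap_nt) {
          run[[length(run)]] <- c(run[[length(run)]], ix[k])
        } else {
          run[[length(run) + 1L]] <- ix[k]
        }
      }
    }
    for (r in run) {
      if (length(r) >= 2L) {
        cid <- cid + 1L
        tab$cluster_id[r] <- cid
      }
    }
  }
  clustered <- tab[!is.na(tab$cluster_id), ]
  cl <- if (nrow(clustered) == 0L) {
    data.table::data.table(
      cluster_id = integer(), scaffold_id = character(),
      family = character(), span_start = integer(), span_end = integer(),
      size = integer(), members = character())
  } else {
    clustered[, list(scaffold_id = scaffold_id[1], family = family[1],
                     span_start = min(start), span_end = max(end),
                     size = .N, members = paste(id, collapse = ",")),
              by = "cluster_id"]
  }
  data.table::setorder(cl, cluster_id)
  list(clusters = cl[], genes = tab[])
}

#' Cluster statistics
#'
#' The headline tandem-array numbers: the fraction of family members
#' inside clusters of at least `min_report_size` genes, how many such
#' clusters exist, the largest cluster, and the fraction of genes with at
#' least one neighbouring same-family homolog (i.e. in any cluster of
#' size 2+).
#'
#' @param clustering result of [find_clusters()].
#' @param family restrict to one family (`NULL` = all genes).
#' @param min_report_size cluster size defining the headline fraction
#'   (default 4).
#' @return A one-row `data.table`.
#' @export
cluster_statistics <- function(clustering, family = NULL,
                               min_report_size = 4L) {
  g <- clustering$genes
  cl <- clustering$clusters
  if (!is.null(family)) {
    fam_wanted <- family            # plain vector: avoid NSE column capture
    g <- g[g$family %in% fam_wanted, ]
    cl <- cl[cl$family %in% fam_wanted, ]
  }
  n <- nrow(g)
  if (n == 0L) {
    return(data.table::data.table(
      n_genes = 0L, frac_in_big_clusters = 0, n_big_clusters = 0L,
      largest_cluster = 0L, frac_with_neighbor = 0))
  }
  big <- cl$cluster_id[cl$size >= min_report_size]
  data.table::data.table(
    n_genes = n,
    frac_in_big_clusters = sum(g$cluster_id %in% big) / n,
    n_big_clusters = length(big),
    largest_cluster = if (nrow(cl) > 0L) max(cl$size) else 0L,
    frac_with_neighbor = sum(!is.na(g$cluster_id)) / n)
}
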