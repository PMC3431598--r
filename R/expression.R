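#' Expression table
#'
#' Genes x samples fragment counts plus the per-gene exonic lengths and
#' per-sample totals needed for FPKM, and sample metadata (species,
#' caste/sex).
#'
#' @param counts integer matrix, genes x samples.
#' @param gene_length_nt per-gene exonic length (nt), recycled names must
#'   match rownames of `counts`.
#' @param meta data.frame with one row per sample: columns `sample`,
#'   `species`, `sex` (e.g. `"worker"` / `"male"`).
#' @param total_fragments per-sample totals; by default the column sums of
#'   `counts` (i.e. the table is taken to be the whole transcriptome).
#' @return Object of class `expression_table`.
#' @export
expression_table <- function(counts, gene_length_nt, meta,
                             total_fragments = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(rownames(counts))) stop("counts needs rownames", call. = FALSE)
  if (length(gene_length_nt) != nrow(counts)) {
    stop("one exonic length per gene required", call. = FALSE)
  }
  if (any(gene_length_nt <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (!all(c("sample", "species", "sex") %in% names(meta)) ||
      nrow(meta) != ncol(counts)) {
    stop("meta must have sample/species/sex rows matching columns", call. = FALSE)
  }
  if (is.null(colnames(counts))) colnames(counts) <- meta$sample
  if (is.null(total_fragments)) total_fragments <- colSums(counts)
  if (any(total_fragments <= 0)) stop("sample totals must be > 0", call. = FALSE)
  structure(list(counts = counts,
                 gene_length_nt = stats::setNames(as.numeric(gene_length_nt),
                                                  rownames(counts)),
                 meta = as.data.frame(meta),
                 total_fragments = stats::setNames(as.numeric(total_fragments),
                                                   colnames(counts))),
            class = "expression_table")
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `FPKM = count * 1e9 / (total_fragments * length_nt)`.
#'
#' @param table an [expression_table()].
#' @return Numeric matrix, genes x samples.
#' @export
compute_fpkm <- function(table) {
  sweep(sweep(table$counts * 1e9, 2, table$total_fragments, "/"),
        1, table$gene_length_nt, "/")
}

#' Median-of-transcriptome expression calls
#'
#' A gene counts as expressed in a sample iff its FPKM is strictly above
#' the median FPKM of that sample's whole transcriptome (all genes in the
#' table, not only chemoreceptors -- supply the full table).
#'
#' @param fpkm FPKM matrix from [compute_fpkm()].
#' @param sample column name or index; `NULL` returns the full logical
#'   matrix.
#' @return Logical vector (or matrix).
#' @export
call_expressed <- function(fpkm, sample = NULL) {
  med <- apply(fpkm, 2, stats::median)
  calls <- sweep(fpkm, 2, med, ">")
  if (is.null(sample)) calls else calls[, sample]
}

#' Two-fold sex-enrichment classification
#'
#' Pure fold-change classifier between two conditions (by default the
#' worker/male contrast): a gene is `a_enriched` when
#' `(fpkm_a + eps) / (fpkm_b + eps) >= fold` and the pluggable
#' significance test passes; symmetrically for `b_enriched`; otherwise
#' `not_de`. The default `de_test` always passes, making this the plain
#' fold-change rule; a count-based binomial test is available via
#' [de_test_binomial()].
#'
#' @param fpkm_a,fpkm_b matched FPKM vectors (same genes).
#' @param fold fold-change threshold (default 2).
#' @param eps pseudocount in FPKM units.
#' @param de_test function(gene index) -> logical.
#' @param labels names for the two directions.
#' @return Character vector of labels.
#' @export
classify_enrichment <- function(fpkm_a, fpkm_b, fold = 2, eps = 0.1,
                                de_test = function(i) TRUE,
                                labels = c("a_enriched", "b_enriched",
                                           "not_de")) {
  stopifnot(length(fpkm_a) == length(fpkm_b), fold >= 1, eps >= 0)
  ratio <- (fpkm_a + eps) / (fpkm_b + eps)
  out <- rep(labels[3], length(ratio))
  sig <- vapply(seq_along(ratio), de_test, logical(1))
  out[ratio >= fold & sig] <- labels[1]
  out[ratio <= 1 / fold & sig] <- labels[2]
  names(out) <- names(fpkm_a)
  out
}

#' Binomial significance stand-in for differential expression
#'
#' A deliberately simple count-based test (not a reimplementation of any
#' external DE engine): pooled counts of a gene in the two conditions are
#' compared against the expected split given the two library sizes with a
#' two-sided exact binomial test.
#'
#' @param counts_a,counts_b pooled fragment counts per gene.
#' @param total_a,total_b library sizes.
#' @param alpha significance level (default 0.05).
#' @return A `de_test` function usable in [classify_enrichment()].
#' @export
de_test_binomial <- function(counts_a, counts_b, total_a, total_b,
                             alpha = 0.05) {
  pr <- total_a / (total_a + total_b)
  function(i) {
    n <- counts_a[i] + counts_b[i]
    if (n == 0) return(FALSE)
    stats::binom.test(counts_a[i], n, p = pr)$p.value <= alpha
  }
}

#' Delineate two-species orthologous groups
#'
#' Returns the smallest clades of a two-species gene tree with bootstrap
#' support at or above the threshold that contain at least one gene from
#' each species. Groups are disjoint: once a clade qualifies, no ancestor
#' of it is reported, and genes in no qualifying clade stay unassigned.
#'
#' @param gene_tree rooted `phylo` containing genes of exactly two
#'   species.
#' @param support_threshold bootstrap threshold (default 70). The root
#'   (which carries no incoming-branch support) is treated as supported.
#' @param species_pattern regex extracting species prefixes.
#' @return `data.table` with `group`, `gene`, `species`.
#' @export
delineate_orthogroups <- function(gene_tree, support_threshold = 70L,
                                  species_pattern = "^(Cf|Hs|Lh|Pb|Am|Nv)") {
  sp <- leaf_species(gene_tree$tip.label, species_pattern)
  species <- sort(unique(sp))
  if (length(species) < 2L) {
    stop("gene tree must contain genes of two species", call. = FALSE)
  }
  if (length(species) > 2L) {
    stop("orthogroup delineation is defined for two species", call. = FALSE)
  }
  ntip <- length(gene_tree$tip.label)
  tips <- tree_clades(gene_tree)
  sup <- node_supports(gene_tree)
  root <- ntip + 1L
  groups <- list()
  assigned <- logical(ntip)
  # postorder so the smallest qualifying clades claim their genes first
  nodes <- c(setdiff(order(vapply(tips, length, integer(1))), seq_len(ntip)))
  for (v in nodes) {
    tv <- tips[[v]]
    if (any(assigned[tv])) next
    supported <- v == root || (!is.na(sup[v - ntip]) &&
                                 sup[v - ntip] >= support_threshold)
    if (supported && length(unique(sp[tv])) == 2L) {
      groups[[length(groups) + 1L]] <- tv
      assigned[tv] <- TRUE
    }
  }
  if (length(groups) == 0L) {
    return(data.table::data.table(group = character(), gene = character(),
                                  species = character()))
  }
  data.table::rbindlist(lapply(seq_along(groups), function(g) {
    data.table::data.table(group = sprintf("OG%03d", g),
                           gene = gene_tree$tip.label[groups[[g]]],
                           species = sp[groups[[g]]])
  }))
}

#' Cross-species expression concordance of orthogroups
#'
#' A group is classifiable iff each species contributes at least one gene
#' with a non-null enrichment label. Within a species, disagreeing labels
#' make the group `conflicting`; otherwise the two species' directions are
#' compared, giving `same_sex` or `different_sex`.
#'
#' @param groups output of [delineate_orthogroups()].
#' @param enrichment named character vector per gene with values
#'   `"worker_enriched"`, `"male_enriched"` or `"not_de"` (as produced by
#'   [classify_enrichment()] with matching labels).
#' @return List with `groups` (`data.table`: group, class) and `summary`
#'   (counts per class).
#' @export
classify_concordance <- function(groups, enrichment) {
  cls <- vapply(split(groups, groups$group), function(g) {
    lab <- enrichment[g$gene]
    per_species <- lapply(split(lab, g$species), function(x) {
      unique(x[!is.na(x) & x != "not_de"])
    })
    if (any(vapply(per_species, length, integer(1)) == 0L)) {
      return("not_classifiable")
    }
    if (any(vapply(per_species, length, integer(1)) > 1L)) {
      return("conflicting")
    }
    dirs <- unlist(per_species)
    if (length(unique(dirs)) == 1L) "same_sex" else "different_sex"
  }, character(1))
  out <- data.table::data.table(group = names(cls), class = unname(cls))
  lev <- c("same_sex", "different_sex", "conflicting", "not_classifiable")
  summ <- data.table::data.table(
    class = lev, n = vapply(lev, function(l) sum(cls == l), integer(1)))
  list(groups = out, summary = summ)
}
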