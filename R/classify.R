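#' Recompute disruption counts for a model
#'
#' Re-derives, from the genome, the two disruption signals used to call
#' pseudogenes: in-exon stop codons (the terminal stop is excluded) and
#' frame-inconsistent breaks between near-adjacent coding segments (a gap
#' shorter than `min_intron_nt` whose length is not a codon multiple).
#'
#' @param model a [gene_model()].
#' @param genome a `genome`.
#' @param config a [pipeline_config()].
#' @return Named integer vector `c(frameshift = , premature_stop = )`.
#' @export
detect_disruptions <- function(model, genome, config = pipeline_config()) {
  lens <- scaffold_lengths(genome)
  if (!model$scaffold_id %in% names(lens) ||
      any(model$exons[, 1] < 1L) ||
      any(model$exons[, 2] > lens[[model$scaffold_id]])) {
    stop("model exons outside genome", call. = FALSE)
  }
  m <- build_model_from_exons(model$id, model$family, model$scaffold_id,
                              model$strand, model$exons, genome, config)
  m$disruptions
}

# Internal: edge proximity of a model (scaffold end or N-run >= 100 nt).
edge_proximity <- function(model, genome, config) {
  ext <- model_extent(model)
  len <- scaffold_lengths(genome)[[model$scaffold_id]]
  near_end <- ext[1] <= config$edge_distance_nt ||
    (len - ext[2]) < config$edge_distance_nt
  runs <- n_runs(genome, model$scaffold_id, min_len = 100L)
  near_n <- FALSE
  if (nrow(runs) > 0L) {
    d <- pmax(runs$start - ext[2], ext[1] - runs$end, 0L)
    near_n <- any(d <= config$edge_distance_nt)
  }
  c(near_scaffold_end = near_end, abuts_N_run = near_n)
}

#' Classify a gene model
#'
#' Applies the fragment-mechanism decision order: (1) a model whose clean
#' ORF reaches `min_intact_aa` with zero disruptions is `intact` (IR
#' models must additionally pass `domain_checker`); (2) any disruption
#' makes it a `pseudogene`; (3) a short clean model within
#' `edge_distance_nt` of a scaffold end or an N-run of 100+ nt is
#' `partial_assembly` (truncated by the draft assembly); (4) anything else
#' is `short_unresolved`.
#'
#' @param model a [gene_model()].
#' @param genome a `genome`.
#' @param config a [pipeline_config()].
#' @param domain_checker function(model) -> logical; the IR domain
#'   requirement (ionotropic-receptor ligand-channel signature). The
#'   default passes everything, i.e. the check is a pluggable slot.
#' @return The model with `status`, `disruptions` and `edge_flags` filled
#'   in.
#' @export
classify_model <- function(model, genome, config = pipeline_config(),
                           domain_checker = function(model) TRUE) {
  dis <- detect_disruptions(model, genome, config)
  # keep predictor-recorded evidence (e.g. query-gap disruptions) that a
  # pure re-derivation from exon coordinates cannot see
  if (!is.null(model$disruptions)) {
    dis <- pmax(dis, model$disruptions[names(dis)])
  }
  flags <- edge_proximity(model, genome, config)
  model$disruptions <- dis
  model$edge_flags <- flags
  long_enough <- model$orf_length_aa >= config$min_intact_aa
  model$status <-
    if (long_enough && sum(dis) == 0L &&
        (model$family != "IR" || isTRUE(domain_checker(model)))) {
      "intact"
    } else if (sum(dis) >= 1L) {
      "pseudogene"
    } else if (any(flags)) {
      "partial_assembly"
    } else {
      "short_unresolved"
    }
  model
}

#' Fragment-mechanism summary
#'
#' Per-family counts and fractions of each status class, plus the
#' fraction of *incomplete* models (everything except `intact`) explained
#' by assembly truncation -- the quantity that separates "pseudogene" from
#' "draft-assembly artefact" as the source of fragmented models.
#'
#' @param models list of classified [gene_model()] objects.
#' @return A `data.table` with one row per family and an `all` row.
#' @export
fragment_mechanism_report <- function(models) {
  tab <- models_to_table(models)
  if (nrow(tab) == 0L) {
    return(data.table::data.table(
      family = character(), n = integer(), intact = integer(),
      pseudogene = integer(), partial_assembly = integer(),
      short_unresolved = integer(), frac_intact = numeric(),
      edge_fraction_of_incomplete = numeric()))
  }
  one <- function(d) {
    n <- nrow(d)
    k <- function(s) sum(d$status == s, na.rm = TRUE)
    inc <- n - k("intact")
    data.table::data.table(
      n = n, intact = k("intact"), pseudogene = k("pseudogene"),
      partial_assembly = k("partial_assembly"),
      short_unresolved = k("short_unresolved"),
      frac_intact = k("intact") / n,
      edge_fraction_of_incomplete =
        if (inc > 0L) k("partial_assembly") / inc else NA_real_)
  }
  per <- tab[, one(.SD), by = "family"]
  all <- cbind(data.table::data.table(family = "all"), one(tab))
  data.table::rbindlist(list(per, all), use.names = TRUE)
}
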