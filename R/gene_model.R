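#' Gene model container
#'
#' A predicted locus with exon structure, translation and classification
#' fields. Exons are stored as a two-column integer matrix (`start`, `end`,
#' 1-based inclusive, forward coordinates) ordered in transcription
#' direction: ascending starts on `+`, descending on `-`. The `translation`
#' holds the protein of the longest disruption-free open reading frame of
#' the model, and `orf_length_aa` equals its length; `full_translation`
#' (when present) is the raw stitched translation across all exons, with
#' `*` marking in-frame stops.
#'
#' @param id gene id.
#' @param family family label, one of `"OR"`, `"GR"`, `"IR"`, `"other"`.
#' @param scaffold_id,strand location.
#' @param exons two-column matrix of exon coordinates in transcription
#'   order.
#' @param translation protein string of the longest clean ORF.
#' @param disruptions named integer vector with elements `frameshift` and
#'   `premature_stop`.
#' @param edge_flags named logical vector with elements
#'   `near_scaffold_end` and `abuts_N_run`.
#' @param status one of `"intact"`, `"pseudogene"`, `"partial_assembly"`,
#'   `"short_unresolved"`, or `NA` before classification.
#' @param full_translation optional raw stitched translation.
#' @param exon_frames optional integer vector of per-exon reading frames.
#' @param ref_query optional id of the reference query used for
#'   prediction.
#' @param clipped logical; `TRUE` when the model was cut by a scaffold
#'   boundary during prediction.
#' @return A `gene_model` object.
#' @export
gene_model <- function(id, family = "other", scaffold_id, strand, exons,
                       translation = "", disruptions = c(frameshift = 0L,
                                                         premature_stop = 0L),
                       edge_flags = c(near_scaffold_end = FALSE,
                                      abuts_N_run = FALSE),
                       status = NA_character_, full_translation = NULL,
                       exon_frames = NULL, ref_query = NULL,
                       clipped = FALSE) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("a gene model needs at least one exon", call. = FALSE)
  if (any(exons[, 1] > exons[, 2])) stop("exon start > end", call. = FALSE)
  o <- order(exons[, 1])
  ov <- nrow(exons) > 1L &&
    any(exons[o, 1][-1] <= exons[o, 2][-nrow(exons)])
  if (ov) stop("exons within one model must not overlap", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  expected <- if (strand == "+") o else rev(o)
  if (!identical(expected, seq_len(nrow(exons)))) {
    stop("exons must be ordered in transcription direction", call. = FALSE)
  }
  structure(list(
    id = as.character(id),
    family = match.arg(family, c("OR", "GR", "IR", "other")),
    scaffold_id = as.character(scaffold_id),
    strand = strand,
    exons = exons,
    translation = as.character(translation),
    orf_length_aa = nchar(translation),
    disruptions = c(frameshift = as.integer(disruptions[["frameshift"]]),
                    premature_stop = as.integer(disruptions[["premature_stop"]])),
    edge_flags = c(near_scaffold_end = isTRUE(edge_flags[["near_scaffold_end"]]),
                   abuts_N_run = isTRUE(edge_flags[["abuts_N_run"]])),
    status = status,
    full_translation = full_translation,
    exon_frames = exon_frames,
    ref_query = ref_query,
    clipped = isTRUE(clipped)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s [%s] %s:%d-%d (%s) %d exon(s), %d aa, status=%s\n",
              x$id, x$family, x$scaffold_id, model_extent(x)[1],
              model_extent(x)[2], x$strand, nrow(x$exons), x$orf_length_aa,
              x$status))
  invisible(x)
}

# Internal: forward-coordinate extent of a model.
model_extent <- function(model) {
  c(min(model$exons[, 1]), max(model$exons[, 2]))
}

#' Summarise a list of gene models as a table
#'
#' @param models list of `gene_model` objects.
#' @return A `data.table`, one row per model.
#' @export
models_to_table <- function(models) {
  if (length(models) == 0L) {
    return(data.table::data.table(
      id = character(), family = character(), scaffold_id = character(),
      strand = character(), start = integer(), end = integer(),
      n_exons = integer(), orf_length_aa = integer(),
      frameshift = integer(), premature_stop = integer(),
      near_scaffold_end = logical(), abuts_N_run = logical(),
      status = character()))
  }
  data.table::rbindlist(lapply(models, function(m) {
    ex <- model_extent(m)
    data.table::data.table(
      id = m$id, family = m$family, scaffold_id = m$scaffold_id,
      strand = m$strand, start = ex[1], end = ex[2],
      n_exons = nrow(m$exons), orf_length_aa = m$orf_length_aa,
      frameshift = m$disruptions[["frameshift"]],
      premature_stop = m$disruptions[["premature_stop"]],
      near_scaffold_end = m$edge_flags[["near_scaffold_end"]],
      abuts_N_run = m$edge_flags[["abuts_N_run"]],
      status = m$status)
  }))
}

#' Write / read gene models as GFF3
#'
#' Emits one `gene`, one `mRNA` and one `CDS` row per exon for each model,
#' 1-based inclusive coordinates, with the phase column computed from
#' cumulative CDS length in transcription order (so on the minus strand
#' phases accrue 3' to 5' along the file). Model-level fields that GFF3
#' has no column for (family, status, translation, disruption counts) are
#' carried in the attribute column so the companion reader round-trips
#' without loss.
#'
#' @param models list of `gene_model` objects.
#' @param path output file.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    ex <- m$exons
    extent <- model_extent(m)
    attrs <- sprintf(
      "ID=%s;family=%s;status=%s;frameshift=%d;premature_stop=%d;near_scaffold_end=%d;abuts_N_run=%d;translation=%s",
      m$id, m$family, ifelse(is.na(m$status), "NA", m$status),
      m$disruptions[["frameshift"]], m$disruptions[["premature_stop"]],
      as.integer(m$edge_flags[["near_scaffold_end"]]),
      as.integer(m$edge_flags[["abuts_N_run"]]), m$translation)
    lines <- c(lines,
      sprintf("%s\tchemoreceptR\tgene\t%d\t%d\t.\t%s\t.\t%s",
              m$scaffold_id, extent[1], extent[2], m$strand, attrs),
      sprintf("%s\tchemoreceptR\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              m$scaffold_id, extent[1], extent[2], m$strand, m$id, m$id))
    # phase of CDS k = nt of transcript needed to reach next codon start
    cumlen <- c(0L, cumsum(ex[, 2] - ex[, 1] + 1L))
    phase <- (3L - (cumlen[seq_len(nrow(ex))] %% 3L)) %% 3L
    cds <- data.frame(start = ex[, 1], end = ex[, 2], phase = phase)
    cds <- cds[order(cds$start), , drop = FALSE]   # file order is ascending
    lines <- c(lines, sprintf(
      "%s\tchemoreceptR\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.t1",
      m$scaffold_id, cds$start, cds$end, m$strand, cds$phase, m$id, m$id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @return `read_gene_models_gff3` returns a list of `gene_model` objects.
#' @export
read_gene_models_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  f <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                         col.names = c("seqid", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attrs"))
  attr_get <- function(a, key) {
    m <- regmatches(a, regexpr(sprintf("(^|;)%s=[^;]*", key), a))
    if (length(m) == 0L) return(NA_character_)
    sub(sprintf("^(;)?%s=", key), "", sub("^;", "", m))
  }
  genes <- f[f$type == "gene", ]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    a <- genes$attrs[i]
    id <- attr_get(a, "ID")
    cds <- f[f$type == "CDS" & grepl(sprintf("Parent=%s.t1", id), f$attrs,
                                     fixed = TRUE), ]
    ex <- as.matrix(cds[, c("start", "end")])
    if (genes$strand[i] == "-") ex <- ex[order(-ex[, 1]), , drop = FALSE]
    else ex <- ex[order(ex[, 1]), , drop = FALSE]
    st <- attr_get(a, "status")
    out[[i]] <- gene_model(
      id = id, family = attr_get(a, "family"),
      scaffold_id = genes$seqid[i], strand = genes$strand[i], exons = ex,
      translation = ifelse(is.na(attr_get(a, "translation")), "",
                           attr_get(a, "translation")),
      disruptions = c(frameshift = as.integer(attr_get(a, "frameshift")),
                      premature_stop = as.integer(attr_get(a, "premature_stop"))),
      edge_flags = c(
        near_scaffold_end = attr_get(a, "near_scaffold_end") == "1",
        abuts_N_run = attr_get(a, "abuts_N_run") == "1"),
      status = if (identical(st, "NA")) NA_character_ else st)
  }
  out
}
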