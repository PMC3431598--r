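#' Construct an HSP table
#'
#' An HSP (high-scoring segment pair) is one local alignment between a
#' protein query and translated genomic DNA. HSPs are kept in a
#' `data.table`, one row per hit, with subject coordinates normalised to
#' the forward strand (`s_start <= s_end`) and the original orientation in
#' `strand`. Query coordinates are amino acids, subject coordinates
#' nucleotides, both 1-based inclusive.
#'
#' @param query_id,scaffold_id character vectors.
#' @param bit_score,e_value numeric vectors (`bit_score >= 0`,
#'   `e_value >= 0`).
#' @param q_start,q_end,s_start,s_end integer coordinate vectors.
#' @param strand `"+"` or `"-"`.
#' @param frame integer in -3..-1, 1..3 (`NA` when unknown).
#' @param genome optional `genome`; if supplied, subject coordinates are
#'   checked against scaffold bounds.
#' @return A `data.table` of class `hsp_table`.
#' @export
hsp_table <- function(query_id = character(), scaffold_id = character(),
                      bit_score = numeric(), e_value = numeric(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), frame = NA_integer_,
                      genome = NULL) {
  h <- data.table::data.table(
    query_id = as.character(query_id),
    scaffold_id = as.character(scaffold_id),
    bit_score = as.numeric(bit_score),
    e_value = as.numeric(e_value),
    q_start = as.integer(q_start),
    q_end = as.integer(q_end),
    s_start = as.integer(s_start),
    s_end = as.integer(s_end),
    strand = as.character(strand),
    frame = as.integer(frame)
  )
  validate_hsps(h, genome = genome)
  data.table::setattr(h, "class", c("hsp_table", class(h)))
  h[]
}

validate_hsps <- function(h, genome = NULL) {
  if (nrow(h) == 0L) return(invisible(h))
  if (any(h$bit_score < 0, na.rm = TRUE)) stop("bit_score must be >= 0", call. = FALSE)
  if (any(h$e_value < 0, na.rm = TRUE)) stop("e_value must be >= 0", call. = FALSE)
  if (any(h$q_start > h$q_end)) stop("q_start must be <= q_end", call. = FALSE)
  if (any(h$s_start > h$s_end)) stop("s_start must be <= s_end", call. = FALSE)
  if (!all(h$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  if (any((h$s_end - h$s_start + 1L) %% 3L != 0L)) {
    stop("HSP nucleotide span must be a multiple of 3", call. = FALSE)
  }
  ok <- is.na(h$frame) | (h$frame %in% c(-3L:-1L, 1L:3L))
  if (!all(ok)) stop("frame must be in -3..-1 or 1..3", call. = FALSE)
  if (!is.null(genome)) {
    len <- scaffold_lengths(genome)
    if (!all(h$scaffold_id %in% names(len))) {
      stop("HSP scaffold not present in genome", call. = FALSE)
    }
    if (any(h$s_start < 1L | h$s_end > len[h$scaffold_id])) {
      stop("HSP coordinates outside scaffold", call. = FALSE)
    }
  }
  invisible(h)
}

#' Read a BLAST-style tabular HSP file
#'
#' Ingests translated-search hits in 12-column tabular format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), or the same with a 13th subject-frame column
#' (`dialect = "blast_tab_frames"`). Minus-strand hits reported with
#' `sstart > send` are normalised to forward coordinates with
#' `strand = "-"`.
#'
#' @param path tabular text file; `#`-prefixed lines are skipped.
#' @param dialect `"blast_tab_std"` or `"blast_tab_frames"`.
#' @return An `hsp_table`. An empty file yields an empty table.
#' @export
read_hsp_table <- function(path, dialect = c("blast_tab_std", "blast_tab_frames")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(hsp_table())
  need <- if (dialect == "blast_tab_std") 12L else 13L
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1L) f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < need) {
      stop(sprintf("line %d: expected >= %d columns, got %d", i, need, length(f)),
           call. = FALSE)
    }
    co <- suppressWarnings(as.numeric(f[c(7, 8, 9, 10)]))
    ev <- suppressWarnings(as.numeric(f[11]))
    bs <- suppressWarnings(as.numeric(f[12]))
    if (anyNA(co) || any(co != round(co)) || is.na(ev) || is.na(bs)) {
      stop(sprintf("line %d: unparseable coordinates or scores", i), call. = FALSE)
    }
    ss <- co[3]; se <- co[4]
    strand <- if (ss <= se) "+" else "-"
    fr <- NA_integer_
    if (dialect == "blast_tab_frames") {
      fr <- suppressWarnings(as.integer(f[13]))
      if (is.na(fr) || !(fr %in% c(-3L:-1L, 1L:3L))) {
        stop(sprintf("line %d: bad frame column", i), call. = FALSE)
      }
    } else if (strand == "+") {
      fr <- as.integer((ss - 1) %% 3 + 1)   # minus-strand frame needs scaffold length
    }
    rows[[k]] <- data.table::data.table(
      query_id = f[1], scaffold_id = f[2], bit_score = bs, e_value = ev,
      q_start = as.integer(co[1]), q_end = as.integer(co[2]),
      s_start = as.integer(min(ss, se)), s_end = as.integer(max(ss, se)),
      strand = strand, frame = fr)
  }
  h <- data.table::rbindlist(rows)
  validate_hsps(h)
  data.table::setattr(h, "class", c("hsp_table", class(h)))
  h[]
}

#' @rdname read_hsp_table
#' @param hsps an `hsp_table`.
#' @export
write_hsp_table <- function(hsps, path) {
  if (nrow(hsps) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  span <- hsps$s_end - hsps$s_start + 1L
  alen <- hsps$q_end - hsps$q_start + 1L
  out <- data.table::data.table(
    qseqid = hsps$query_id, sseqid = hsps$scaffold_id,
    pident = 100, length = alen, mismatch = 0L, gapopen = 0L,
    qstart = hsps$q_start, qend = hsps$q_end,
    sstart = ifelse(hsps$strand == "+", hsps$s_start, hsps$s_end),
    send = ifelse(hsps$strand == "+", hsps$s_end, hsps$s_start),
    evalue = hsps$e_value, bitscore = hsps$bit_score,
    sframe = ifelse(is.na(hsps$frame), 1L, hsps$frame))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
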