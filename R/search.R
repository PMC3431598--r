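# Built-in translated protein-vs-genome search: 6-frame translation of the
# genome, exact 6-mer amino-acid seeding via a hashed index, and local
# Smith-Waterman extension (Biostrings::pairwiseAlignment, BLOSUM62) inside
# seed-defined windows. Scores are mapped to bit scores / e-values with the
# usual gapped BLOSUM62 Karlin-Altschul constants (lambda = 0.267,
# K = 0.041). This is the package's own lightweight search; precomputed
# tabular hits can be supplied instead via read_hsp_table().

.aa_alphabet <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V","B","J","Z","X","*")

.aa_map <- local({
  m <- rep(NA_integer_, 128L)
  for (i in seq_along(.aa_alphabet)) m[utf8ToInt(.aa_alphabet[i])] <- i - 1L
  m
})

# Internal: 0-based integer encoding of an amino-acid string (unknown
# characters map to X).
aa_encode <- function(s) {
  a <- .aa_map[utf8ToInt(s)]
  a[is.na(a)] <- match("X", .aa_alphabet) - 1L
  a
}

aa_codes <- function(s, k = 6L) {
  a <- .aa_map[utf8ToInt(s)]
  n <- length(a)
  if (n < k) return(integer())
  code <- a[1:(n - k + 1L)]
  for (j in 2:k) code <- code + a[j:(n - k + j)] * 25L^(j - 1L)
  code
}

# Internal: BLOSUM62 reordered to the package alphabet.
.b62_ordered <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      B <- get_blosum62()
      cache <<- B[.aa_alphabet, .aa_alphabet]
    }
    cache
  }
})

#' Build a translated-search index for a genome
#'
#' Precomputes the six frame translations of every scaffold and a hashed
#' 6-mer amino-acid index over them. Building the index once and reusing it
#' across queries and pipeline rounds is what makes the iterative
#' annotation affordable.
#'
#' @param genome a `genome`.
#' @return An object of class `search_index`.
#' @export
build_search_index <- function(genome) {
  frames <- list()
  meta <- list()
  fid <- 0L
  for (sc in names(genome)) {
    L <- length(genome[[sc]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") genome[[sc]] else
        Biostrings::reverseComplement(genome[[sc]])
      for (o in 0:2) {
        if (L - o < 3L) next
        fid <- fid + 1L
        sub <- Biostrings::subseq(s, o + 1L, L)
        sub <- Biostrings::subseq(sub, 1L, length(sub) - length(sub) %% 3L)
        aa <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
        frames[[fid]] <- aa
        meta[[fid]] <- data.table::data.table(
          frame_id = fid, scaffold_id = sc, strand = strand,
          offset = o, scaffold_len = L, aa_len = nchar(aa))
      }
    }
  }
  meta <- data.table::rbindlist(meta)
  idx <- data.table::rbindlist(lapply(seq_len(nrow(meta)), function(i) {
    cd <- aa_codes(frames[[meta$frame_id[i]]])
    if (length(cd) == 0L) return(NULL)
    dt <- data.table::data.table(code = cd, frame_id = meta$frame_id[i],
                                 pos = seq_along(cd))
    dt[!is.na(dt$code)]
  }))
  data.table::setkey(idx, code)
  structure(list(frames = frames, meta = meta, index = idx,
                 genome_nt = sum(scaffold_lengths(genome))),
            class = "search_index")
}

# Internal: map an aa range in a frame to forward nucleotide coordinates.
frame_to_nt <- function(meta_row, aa_start, aa_end) {
  o <- meta_row$offset
  L <- meta_row$scaffold_len
  if (meta_row$strand == "+") {
    c(o + 3L * (aa_start - 1L) + 1L, o + 3L * aa_end)
  } else {
    c(L - (o + 3L * aa_end) + 1L, L - (o + 3L * (aa_start - 1L)))
  }
}

#' Run the built-in translated search
#'
#' @param index a `search_index` from [build_search_index()].
#' @param queries named character vector or `AAStringSet` of protein
#'   queries.
#' @param max_evalue loose reporting ceiling; the pipeline's own e-value
#'   gate is applied later by [filter_hsps()].
#' @param seed_cluster_aa seeds within this many aa of each other (same
#'   frame) share one alignment window.
#' @param window_pad_aa padding added around a seed cluster before local
#'   alignment.
#' @return An `hsp_table`.
#' @export
search_hsps <- function(index, queries, max_evalue = 10,
                        seed_cluster_aa = 50L, window_pad_aa = 10L) {
  if (methods::is(queries, "AAStringSet")) {
    queries <- stats::setNames(as.character(queries), names(queries))
  }
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    stop("queries must be named", call. = FALSE)
  }
  B62 <- .b62_ordered()
  out <- list()
  for (qn in names(queries)) {
    qseq <- queries[[qn]]
    qlen <- nchar(qseq)
    if (qlen < 6L) next
    qcodes <- aa_codes(qseq)
    qcodes <- qcodes[!is.na(qcodes)]
    if (length(qcodes) == 0L) next
    hits <- index$index[data.table::data.table(code = unique(qcodes)),
                        nomatch = NULL]
    if (nrow(hits) == 0L) next
    data.table::setorder(hits, frame_id, pos)
    # seed clusters become alignment windows; align them all in one call
    win <- list()
    for (f in unique(hits$frame_id)) {
      pos <- hits$pos[hits$frame_id == f]
      mrow <- index$meta[index$meta$frame_id == f, ]
      grp <- cumsum(c(1L, diff(pos) > seed_cluster_aa))
      for (g in unique(grp)) {
        p <- pos[grp == g]
        w0 <- max(1L, min(p) - window_pad_aa)
        w1 <- min(mrow$aa_len, max(p) + 5L + window_pad_aa)
        win[[length(win) + 1L]] <- list(
          f = f, w0 = w0, subj = substr(index$frames[[f]], w0, w1))
      }
    }
    if (length(win) == 0L) next
    qenc <- aa_encode(qseq)
    for (k in seq_along(win)) {
      mrow <- index$meta[index$meta$frame_id == win[[k]]$f, ]
      frame_str <- index$frames[[win[[k]]$f]]
      # one window can hold several HSPs (e.g. two exons split by a short
      # intron, or the two halves of a disrupted exon): align, then
      # recurse into the unmatched flanks of the window
      stack <- list(c(win[[k]]$w0,
                      win[[k]]$w0 + nchar(win[[k]]$subj) - 1L))
      depth <- 0L
      while (length(stack) > 0L && depth < 12L) {
        depth <- depth + 1L
        rng <- stack[[1]]
        stack[[1]] <- NULL
        if (rng[2] - rng[1] + 1L < 10L) next
        al <- .sw_align(qenc,
                        aa_encode(substr(frame_str, rng[1], rng[2])), B62,
                        gap_open = 12, gap_ext = 1, xdrop = 12)
        sc <- al$score
        if (sc <= 0) next
        ss_aa <- rng[1] + al$s_start - 1L
        se_aa <- rng[1] + al$s_end - 1L
        bits <- (0.267 * sc + 3.19) / log(2)
        ev <- index$genome_nt * qlen * 2^(-bits)
        if (ev <= max_evalue) {
          nt <- frame_to_nt(mrow, ss_aa, se_aa)
          out[[length(out) + 1L]] <- data.table::data.table(
            query_id = qn, scaffold_id = mrow$scaffold_id,
            bit_score = round(bits, 1), e_value = ev,
            q_start = al$q_start, q_end = al$q_end,
            s_start = nt[1], s_end = nt[2],
            strand = mrow$strand,
            frame = if (mrow$strand == "+") mrow$offset + 1L else
              -(mrow$offset + 1L))
        }
        if (sc >= 15) {
          stack[[length(stack) + 1L]] <- c(rng[1], ss_aa - 1L)
          stack[[length(stack) + 1L]] <- c(se_aa + 1L, rng[2])
        }
      }
    }
  }
  if (length(out) == 0L) return(hsp_table())
  h <- unique(data.table::rbindlist(out),
              by = c("query_id", "scaffold_id", "frame", "s_start", "s_end"))
  validate_hsps(h)
  data.table::setattr(h, "class", c("hsp_table", class(h)))
  h[]
}

#' HSP source backed by the built-in search
#'
#' Returns a function `f(queries)` yielding an [hsp_table()], suitable as
#' the pluggable `hsp_source` of [run_iterative_pipeline()]. The genome
#' index is built once and cached in the closure.
#'
#' @param genome a `genome`.
#' @param ... passed on to [search_hsps()].
#' @return A function of one argument (`queries`).
#' @export
builtin_hsp_source <- function(genome, ...) {
  index <- build_search_index(genome)
  function(queries) search_hsps(index, queries, ...)
}
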