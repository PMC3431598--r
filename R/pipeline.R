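#' Filter HSPs by e-value and relative bit-score
#'
#' Applies the two-stage gate used by the annotation pipeline: hits with
#' e-value above `evalue_cutoff` are removed first; the mean bit-score of
#' the top `ceil(top_fraction * N)` remaining hits is then computed, and
#' any hit scoring below `score_fraction` of that mean is discarded
#' (strictly below: ties with the threshold are retained). With the
#' defaults this is "keep e <= 1e-5, then drop hits under 25% of the mean
#' of the top 75%".
#'
#' The average is computed over the whole search run by default
#' (`score_filter_scope = "global"`); `"per_query"` restricts it to each
#' query's own hits.
#'
#' @param hsps an [hsp_table()].
#' @param config a [pipeline_config()].
#' @return The retained rows, in input order.
#' @export
filter_hsps <- function(hsps, config = pipeline_config()) {
  if (nrow(hsps) == 0L) return(hsps)
  h <- hsps[hsps$e_value <= config$evalue_cutoff, ]
  if (nrow(h) == 0L) return(h)
  thresh_of <- function(scores) {
    k <- ceiling(config$top_fraction * length(scores))
    config$score_fraction * mean(sort(scores, decreasing = TRUE)[seq_len(k)])
  }
  keep <- if (config$score_filter_scope == "global") {
    h$bit_score >= thresh_of(h$bit_score)
  } else {
    thr <- vapply(split(h$bit_score, h$query_id), thresh_of, numeric(1))
    h$bit_score >= thr[h$query_id]
  }
  h[keep, ]
}

#' Chain HSPs into putative coding regions
#'
#' Within each (query, scaffold, strand) group, HSPs are sorted in
#' transcription order (ascending subject start on `+`, descending subject
#' end on `-`) and consecutive HSPs are linked when (1) the nucleotide gap
#' between them is at most `chain_gap_nt` and (2) the upstream member's
#' query start is strictly N-terminal to the downstream member's. The
#' second criterion is what prevents two neighbouring paralogs from being
#' concatenated into one chain. Chains are the connected components of
#' these consecutive links; an unlinked HSP is a chain of size 1.
#'
#' @param hsps an [hsp_table()] (already filtered).
#' @param config a [pipeline_config()].
#' @return The HSP table with a `chain_id` column added, ordered by chain
#'   and transcription position.
#' @export
chain_hsps <- function(hsps, config = pipeline_config()) {
  h <- data.table::copy(data.table::as.data.table(hsps))
  if (nrow(h) == 0L) {
    h$chain_id <- integer()
    return(h)
  }
  h$.row <- seq_len(nrow(h))
  h$chain_id <- NA_integer_
  cid <- 0L
  grp <- split(seq_len(nrow(h)),
               list(h$query_id, h$scaffold_id, h$strand), drop = TRUE)
  for (ix in grp) {
    strand <- h$strand[ix[1]]
    ord <- if (strand == "+") ix[order(h$s_start[ix], h$s_end[ix])]
           else ix[order(-h$s_end[ix], -h$s_start[ix])]
    cid <- cid + 1L
    h$chain_id[ord[1]] <- cid
    if (length(ord) > 1L) {
      for (k in 2:length(ord)) {
        cur <- ord[k - 1L]; nxt <- ord[k]
        gap <- if (strand == "+") h$s_start[nxt] - h$s_end[cur] - 1L
               else h$s_start[cur] - h$s_end[nxt] - 1L
        linked <- gap <= config$chain_gap_nt &&
          h$q_start[cur] < h$q_start[nxt]
        if (!linked) cid <- cid + 1L
        h$chain_id[nxt] <- cid
      }
    }
  }
  data.table::setorder(h, chain_id, .row)
  h$.row <- NULL
  h[]
}

# Internal: one row per chain with extent and best score.
chain_summary <- function(chained) {
  if (nrow(chained) == 0L) {
    return(data.table::data.table(
      chain_id = integer(), query_id = character(), scaffold_id = character(),
      strand = character(), start = integer(), end = integer(),
      best_bit = numeric()))
  }
  dt <- data.table::as.data.table(chained)
  dt[, list(query_id = query_id[1], scaffold_id = scaffold_id[1],
            strand = strand[1], start = min(s_start), end = max(s_end),
            best_bit = max(bit_score)),
     by = "chain_id"]
}

#' Merge chains into loci
#'
#' Chains on the same scaffold and strand whose genomic extents overlap
#' are merged into one putative gene locus; adjacent but disjoint chains
#' stay separate (the chaining gap rule already absorbs within-gene gaps).
#' Each locus records a reference query -- the query owning the maximum
#' bit-score HSP in the region, ties broken lexicographically -- and a
#' flanked extent (`region_flank_nt` either side, clipped to scaffold
#' bounds when a genome is supplied).
#'
#' @param chained output of [chain_hsps()].
#' @param config a [pipeline_config()].
#' @param genome optional `genome` used to clip flanks.
#' @return A list with `loci` (a `data.table`: `locus_id`, location,
#'   extent, `ref_query`, flanks) and `hsps` (the input rows with a
#'   `locus_id` column).
#' @export
merge_chains_to_loci <- function(chained, config = pipeline_config(),
                                 genome = NULL) {
  cs <- chain_summary(chained)
  h <- data.table::copy(data.table::as.data.table(chained))
  if (nrow(cs) == 0L) {
    return(list(loci = data.table::data.table(
      locus_id = integer(), scaffold_id = character(), strand = character(),
      start = integer(), end = integer(), flank_start = integer(),
      flank_end = integer(), ref_query = character(), n_chains = integer()),
      hsps = h))
  }
  lens <- if (is.null(genome)) NULL else scaffold_lengths(genome)
  cs$locus_id <- NA_integer_
  lid <- 0L
  for (key in unique(paste(cs$scaffold_id, cs$strand))) {
    sel <- which(paste(cs$scaffold_id, cs$strand) == key)
    sel <- sel[order(cs$start[sel], cs$end[sel])]
    cur_end <- -1L
    for (i in sel) {
      if (cs$start[i] > cur_end) {
        lid <- lid + 1L
        cur_end <- cs$end[i]
      } else {
        cur_end <- max(cur_end, cs$end[i])
      }
      cs$locus_id[i] <- lid
    }
  }
  h <- merge(h, cs[, c("chain_id", "locus_id")], by = "chain_id", sort = FALSE)
  loci <- cs[, list(scaffold_id = scaffold_id[1], strand = strand[1],
                    start = min(start), end = max(end),
                    n_chains = .N),
             by = "locus_id"]
  # reference query: maximum member bit-score, lexicographic tie-break
  best <- data.table::as.data.table(h)[
    order(-bit_score, query_id), list(ref_query = query_id[1]),
    by = "locus_id"]
  loci <- merge(loci, best, by = "locus_id", sort = TRUE)
  loci$flank_start <- pmax(1L, loci$start - config$region_flank_nt)
  fe <- loci$end + config$region_flank_nt
  if (!is.null(lens)) fe <- pmin(as.integer(lens[loci$scaffold_id]), fe)
  loci$flank_end <- as.integer(fe)
  data.table::setorder(loci, locus_id)
  list(loci = loci[], hsps = h[])
}

# Internal: stop codons on the forward strand of a codon string.
.stops <- c("TAA", "TAG", "TGA")

# Internal: transcription-space character fetch relative to a forward-
# coordinate anchor. rel = 0 addresses the anchor base itself; positive
# rel moves 3'-ward along the transcript.
tx_chars <- function(genome, scaffold_id, strand, anchor, from_rel, to_rel) {
  len <- scaffold_lengths(genome)[[scaffold_id]]
  if (strand == "+") {
    lo <- anchor + from_rel; hi <- anchor + to_rel
  } else {
    lo <- anchor - to_rel; hi <- anchor - from_rel
  }
  lo2 <- max(1L, lo); hi2 <- min(len, hi)
  if (lo2 > hi2) return(list(s = "", pad = 0L))
  s <- as.character(genome_subseq(genome, scaffold_id, lo2, hi2, strand))
  pad <- if (strand == "+") lo2 - lo else hi - hi2
  list(s = s, pad = pad)   # pad = bases clipped at the 5' (rel) side
}

# Internal: refine exon/intron junctions against the reference query, the
# way homology-based predictors place splice sites: candidate shifts of
# up to 10 codons either side must yield canonical GT...AG intron ends,
# and among those the translated junction context most similar to the
# query (BLOSUM62 over `w` flanking residues) wins. Junctions whose gap
# is below min_intron_nt (candidate frameshifts) are left untouched.
refine_junctions <- function(exons, q_end_prev, query_seq, scaffold_id,
                             strand, genome, config, w = 8L, shift = 25L) {
  dq_end <- integer(nrow(exons))     # codon shift applied to each exon 3' end
  dq_start <- integer(nrow(exons))   # codon shift applied to each exon 5' start
  sc_tail <- rep(NA_real_, nrow(exons))  # query support 5' of junction k-1|k
  sc_head <- rep(NA_real_, nrow(exons))  # query support 3' of junction k-1|k
  w_tail <- rep(NA_integer_, nrow(exons))
  w_head <- rep(NA_integer_, nrow(exons))
  no_splice <- rep(FALSE, nrow(exons))   # no GT..AG configuration at all
  out <- function() list(exons = exons, dq_end = dq_end, dq_start = dq_start,
                         sc_tail = sc_tail, sc_head = sc_head,
                         w_tail = w_tail, w_head = w_head,
                         no_splice = no_splice)
  if (nrow(exons) < 2L || is.null(query_seq)) return(out())
  code <- Biostrings::GENETIC_CODE
  B62 <- get_blosum62()
  translate_str <- function(s) {
    n <- nchar(s) %/% 3L
    if (n == 0L) return("")
    cods <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- code[cods]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  score_aa <- function(a1, a2) {
    n <- min(nchar(a1), nchar(a2))
    if (n == 0L) return(0)
    v1 <- strsplit(substr(a1, 1L, n), "")[[1]]
    v2 <- strsplit(substr(a2, 1L, n), "")[[1]]
    ok <- v1 %in% rownames(B62) & v2 %in% rownames(B62)
    sum(B62[cbind(v1[ok], v2[ok])])
  }
  qlen <- nchar(query_seq)
  for (k in 2:nrow(exons)) {
    prev <- exons[k - 1L, ]; nxt <- exons[k, ]
    gap <- if (strand == "+") nxt[1] - prev[2] - 1L else prev[1] - nxt[2] - 1L
    if (gap < config$min_intron_nt) next
    E <- if (strand == "+") prev[2] else prev[1]   # prev exon 3' end (fwd)
    S <- if (strand == "+") nxt[1] else nxt[2]     # next exon 5' start (fwd)
    span <- 3L * (w + shift) + 6L
    fe <- tx_chars(genome, scaffold_id, strand, E, -span + 1L, span)
    fs <- tx_chars(genome, scaffold_id, strand, S, -span, span - 1L)
    if (fe$pad > 0L || fs$pad > 0L) next
    # rel position r (from anchor) maps to index span + r in fe$s,
    # span + 1 + r in fs$s
    e_at <- function(r) substr(fe$s, span + r, span + r)
    s_at <- function(r) substr(fs$s, span + 1L + r, span + 1L + r)
    qe <- q_end_prev[k - 1L]
    plen <- prev[2] - prev[1] + 1L
    nlen <- nxt[2] - nxt[1] + 1L
    junction_parts <- function(a, b) {
      wp <- min(w, (plen + 3L * a) %/% 3L, max(0L, qe + a))
      wn <- min(w, (nlen - 3L * b) %/% 3L, max(0L, qlen - qe - a))
      tail_aa <- translate_str(substr(fe$s, span + 3L * a - 3L * wp + 1L,
                                      span + 3L * a))
      head_aa <- translate_str(substr(fs$s, span + 1L + 3L * b,
                                      span + 3L * b + 3L * wn))
      q_tail <- if (wp > 0L) substr(query_seq, qe + a - wp + 1L, qe + a) else ""
      q_head <- if (wn > 0L) substr(query_seq, qe + a + 1L, qe + a + wn) else ""
      c(tail = score_aa(q_tail, tail_aa), head = score_aa(q_head, head_aa),
        wp = wp, wn = wn)
    }
    junction_score <- function(a, b) sum(junction_parts(a, b)[1:2])
    sc0 <- junction_score(0L, 0L)           # keep-original baseline
    best <- NULL
    for (a in -shift:shift) {
      if (plen + 3L * a < 9L) next
      if (paste0(e_at(3L * a + 1L), e_at(3L * a + 2L)) != "GT") next
      for (b in -shift:shift) {
        if (nlen - 3L * b < 9L) next
        gap2 <- gap - 3L * a + 3L * b
        if (gap2 < 4L) next
        if (paste0(s_at(3L * b - 2L), s_at(3L * b - 1L)) != "AG") next
        sc <- junction_score(a, b)
        cost <- abs(a) + abs(b)
        if (is.null(best) || sc > best$sc ||
            (sc == best$sc && cost < best$cost)) {
          best <- list(a = a, b = b, sc = sc, cost = cost)
        }
      }
    }
    # only move a junction when a canonical GT-AG candidate genuinely
    # explains the query better than the current boundary
    a_fin <- 0L; b_fin <- 0L
    if (!is.null(best) && (best$sc > sc0 + 2 || best$cost == 0L)) {
      if (strand == "+") {
        exons[k - 1L, 2] <- prev[2] + 3L * best$a
        exons[k, 1] <- nxt[1] + 3L * best$b
      } else {
        exons[k - 1L, 1] <- prev[1] - 3L * best$a
        exons[k, 2] <- nxt[2] - 3L * best$b
      }
      dq_end[k - 1L] <- best$a
      dq_start[k] <- best$b
      a_fin <- best$a; b_fin <- best$b
    }
    parts <- junction_parts(a_fin, b_fin)
    sc_tail[k] <- parts[["tail"]]; sc_head[k] <- parts[["head"]]
    w_tail[k] <- parts[["wp"]]; w_head[k] <- parts[["wn"]]
    no_splice[k] <- is.null(best)
  }
  out()
}

# Internal: cached BLOSUM62 matrix.
get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- get("BLOSUM62", envir = e)
    }
    cache
  }
})

# Internal: read one codon in transcription orientation; start = 5'-most
# transcription position (forward coord of the codon start on '+', forward
# coord of the codon *end* is start+2 either way since we pass fwd start).
read_codon <- function(genome, scaffold_id, fwd_start, strand) {
  as.character(genome_subseq(genome, scaffold_id, fwd_start, fwd_start + 2L,
                             strand))
}

#' Predict a gene model at a locus (HSP stitcher)
#'
#' The built-in stand-in for an external homology-based predictor: the
#' reference query's HSPs in the locus are placed in transcription order,
#' trimmed where they overlap on the query (the lower-scoring side loses
#' whole codons), and emitted as exons. Terminal exons are extended within
#' the locus flank to the nearest in-frame start codon (5') and stop codon
#' (3'). Disruptions -- in-exon stop codons and frame-inconsistent breaks
#' between near-adjacent segments -- are recorded on the model rather than
#' causing failure, which is what lets pseudogenes be annotated at all.
#'
#' @param locus one row of the `loci` table from
#'   [merge_chains_to_loci()].
#' @param locus_hsps HSP rows carrying this locus's `locus_id`.
#' @param genome a `genome`.
#' @param config a [pipeline_config()].
#' @param id id for the resulting model.
#' @param family family label.
#' @param query_seq amino-acid sequence of the reference query; when
#'   supplied, exon/intron junctions are refined against it (GT...AG
#'   signal + translated-context similarity).
#' @return A [gene_model()].
#' @export
predict_gene <- function(locus, locus_hsps, genome,
                         config = pipeline_config(), id = NULL,
                         family = "other", query_seq = NULL) {
  hs <- data.table::as.data.table(locus_hsps)
  hs <- hs[hs$query_id == locus$ref_query &
             hs$scaffold_id == locus$scaffold_id &
             hs$strand == locus$strand, ]
  if (nrow(hs) == 0L) stop("locus has no supporting HSPs", call. = FALSE)
  strand <- locus$strand
  if (strand == "+") data.table::setorder(hs, s_start) else
    data.table::setorder(hs, -s_end)

  # Resolve duplicated query coverage between consecutive segments, whole
  # codons. Overlap usually comes from soft alignment edges on both sides
  # of a junction, so it is split at the midpoint; the splice-signal
  # refinement below then pins the exact boundary. A segment fully
  # contained in its neighbour's query span is dropped (the lower-scoring
  # one loses).
  keep <- rep(TRUE, nrow(hs))
  i <- 1L
  while (i < nrow(hs)) {
    if (!keep[i]) { i <- i + 1L; next }
    j <- i + 1L
    while (j <= nrow(hs) && !keep[j]) j <- j + 1L
    if (j > nrow(hs)) break
    ov <- hs$q_end[i] - hs$q_start[j] + 1L
    if (ov > 0L) {
      cut_i <- as.integer(ceiling(ov / 2)); cut_j <- ov - cut_i
      span_i <- hs$q_end[i] - hs$q_start[i] + 1L
      span_j <- hs$q_end[j] - hs$q_start[j] + 1L
      if (ov >= span_i || ov >= span_j) {
        # containment: drop the weaker segment entirely
        if (hs$bit_score[j] < hs$bit_score[i]) keep[j] <- FALSE
        else keep[i] <- FALSE
      } else {
        hs$q_end[i] <- hs$q_end[i] - cut_i
        if (strand == "+") hs$s_end[i] <- hs$s_end[i] - 3L * cut_i
        else hs$s_start[i] <- hs$s_start[i] + 3L * cut_i
        hs$q_start[j] <- hs$q_start[j] + cut_j
        if (strand == "+") hs$s_start[j] <- hs$s_start[j] + 3L * cut_j
        else hs$s_end[j] <- hs$s_end[j] - 3L * cut_j
      }
    }
    if (keep[i] && keep[j]) i <- j
  }
  hs <- hs[keep, ]
  exons <- cbind(start = hs$s_start, end = hs$s_end)
  rj <- refine_junctions(exons, hs$q_end, query_seq, locus$scaffold_id,
                         strand, genome, config)
  exons <- rj$exons
  slen <- scaffold_lengths(genome)[[locus$scaffold_id]]
  clipped <- FALSE

  # 5' extension of the first exon to the nearest in-frame ATG
  first <- 1L
  repeat {
    cstart <- if (strand == "+") exons[first, 1] else exons[first, 2] - 2L
    codon <- read_codon(genome, locus$scaffold_id, cstart, strand)
    if (codon == "ATG") break
    nxt <- if (strand == "+") exons[first, 1] - 3L else exons[first, 2] + 3L - 2L
    fwd_lo <- if (strand == "+") nxt else nxt
    if (fwd_lo < max(1L, locus$flank_start) ||
        (fwd_lo + 2L) > min(slen, locus$flank_end)) {
      if (fwd_lo < 1L || fwd_lo + 2L > slen) clipped <- TRUE
      break
    }
    codon2 <- read_codon(genome, locus$scaffold_id, fwd_lo, strand)
    if (codon2 %in% .stops || grepl("N", codon2)) break
    if (strand == "+") exons[first, 1] <- exons[first, 1] - 3L
    else exons[first, 2] <- exons[first, 2] + 3L
  }

  # 3' extension of the last exon to the next in-frame stop
  last <- nrow(exons)
  repeat {
    cstart <- if (strand == "+") exons[last, 2] - 2L else exons[last, 1]
    codon <- read_codon(genome, locus$scaffold_id, cstart, strand)
    if (codon %in% .stops) break
    nxt <- if (strand == "+") exons[last, 2] + 1L else exons[last, 1] - 3L
    if (nxt < max(1L, locus$flank_start) ||
        (nxt + 2L) > min(slen, locus$flank_end)) {
      if (nxt < 1L || nxt + 2L > slen) clipped <- TRUE
      break
    }
    codon2 <- read_codon(genome, locus$scaffold_id, nxt, strand)
    if (grepl("N", codon2)) break
    if (strand == "+") exons[last, 2] <- exons[last, 2] + 3L
    else exons[last, 1] <- exons[last, 1] - 3L
  }

  # Hidden-disruption scan. A real intron leaves the reference query
  # supported on BOTH sides of the junction; when the aligner has skipped
  # a broken piece of the gene (stop codon or frameshift splitting an
  # exon), the query instead continues with the skipped content, so the
  # downstream junction context scores far below the upstream one (or
  # vice versa), and the query coverage jumps. Such imbalanced junctions
  # are counted as disruptions; the type is read from the in-frame
  # continuation (stop codon within the skipped stretch -> premature
  # stop, otherwise frameshift).
  extra_fs_at <- integer()
  extra_stop_at <- integer()
  if (!is.null(query_seq) && nrow(exons) > 1L) {
    exon_aa <- (exons[, 2] - exons[, 1] + 1L) %/% 3L
    for (k in 2:nrow(exons)) {
      gap_nt <- if (strand == "+") exons[k, 1] - exons[k - 1L, 2] - 1L
                else exons[k - 1L, 1] - exons[k, 2] - 1L
      if (gap_nt < config$min_intron_nt) next
      qe_adj <- hs$q_end[k - 1L] + rj$dq_end[k - 1L]
      qs_adj <- hs$q_start[k] + rj$dq_start[k]
      qgap <- qs_adj - qe_adj - 1L
      st <- rj$sc_tail[k]; sh <- rj$sc_head[k]
      imbalanced <- !is.na(st) && !is.na(sh) &&
        !is.na(rj$w_tail[k]) && rj$w_tail[k] >= 4L &&
        !is.na(rj$w_head[k]) && rj$w_head[k] >= 4L &&
        max(st, sh) >= 25 && min(st, sh) < 0.4 * max(st, sh)
      if (isTRUE(getOption("chemoreceptR.debug_scan"))) {
        message(sprintf(
          "junction %d: qgap=%d gap_nt=%d sc_tail=%.0f sc_head=%.0f imb=%s",
          k, qgap, gap_nt, st, sh, imbalanced))
      }
      R <- if (strand == "+") {
        as.character(genome_subseq(genome, locus$scaffold_id,
                                   exons[k - 1L, 2] + 1L, exons[k, 1] - 1L,
                                   strand))
      } else {
        as.character(genome_subseq(genome, locus$scaffold_id,
                                   exons[k, 2] + 1L, exons[k - 1L, 1] - 1L,
                                   strand))
      }
      at <- sum(exon_aa[seq_len(k - 1L)])
      # One flank strongly supported, the other scoring at or below
      # chance despite contiguous query coverage: the exon sequence on
      # the weak side does not continue the query in any codon-grid
      # phasing -- an indel at the boundary
      if (!is.na(st) && !is.na(sh) && min(st, sh) <= 0 &&
          max(st, sh) >= 25 && qgap < 4L) {
        extra_fs_at <- c(extra_fs_at, at)
        next
      }
      # An indel right at an exon boundary knocks the splice site off the
      # codon grid: the affected side's junction context stays poor at
      # every whole-codon shift, but moving that boundary by 1-2 nt
      # (i.e. admitting a frameshift) repairs it. Test exactly that.
      if (!is.na(st) && !is.na(sh) && min(st, sh) < 5 &&
          max(st, sh) >= 25 && qgap < 4L) {
        qe_anchor <- hs$q_end[k - 1L] + rj$dq_end[k - 1L]
        repaired <- FALSE
        for (d in c(-2L, -1L, 1L, 2L)) {
          sc_d <- if (sh <= st) {
            # re-phase the downstream exon start by d nt
            s0 <- if (strand == "+") exons[k, 1] + d else exons[k, 2] - d
            ctx <- tryCatch(translate_dna(genome_subseq(
              genome, locus$scaffold_id,
              if (strand == "+") s0 else s0 - 23L,
              if (strand == "+") s0 + 23L else s0, strand)),
              error = function(e) "")
            qctx <- substr(query_seq, qe_anchor + 1L, qe_anchor + 8L)
            sum(strsplit(ctx, "")[[1]][seq_len(min(8L, nchar(ctx), nchar(qctx)))] ==
                  strsplit(qctx, "")[[1]][seq_len(min(8L, nchar(ctx), nchar(qctx)))])
          } else {
            e0 <- if (strand == "+") exons[k - 1L, 2] + d else exons[k - 1L, 1] - d
            ctx <- tryCatch(translate_dna(genome_subseq(
              genome, locus$scaffold_id,
              if (strand == "+") e0 - 23L else e0,
              if (strand == "+") e0 else e0 + 23L, strand)),
              error = function(e) "")
            qctx <- substr(query_seq, max(1L, qe_anchor - 7L), qe_anchor)
            sum(strsplit(ctx, "")[[1]][seq_len(min(8L, nchar(ctx), nchar(qctx)))] ==
                  strsplit(qctx, "")[[1]][seq_len(min(8L, nchar(ctx), nchar(qctx)))])
          }
          if (isTRUE(sc_d >= 6L)) { repaired <- TRUE; break }
        }
        if (repaired) {
          extra_fs_at <- c(extra_fs_at, at)
          next
        }
      }
      if (!imbalanced || qgap < 4L) next
      # an undetected *clean* exon also leaves a query-coverage hole with
      # an unsupported flank; if the missing query segment is present in
      # the junction DNA at high identity with no stop inside it, the
      # model is merely incomplete, not disrupted
      piece <- substr(query_seq, qe_adj + 1L, qs_adj - 1L)
      if (nchar(piece) >= 6L) {
        B62o <- get_blosum62()[.aa_alphabet, .aa_alphabet]
        clean_hit <- FALSE
        for (o in 0:2) {
          if (nchar(R) - o < 9L) next
          aa_o <- translate_dna(Biostrings::DNAString(
            substr(R, o + 1L, nchar(R))))
          if (nchar(aa_o) < 3L) next
          al <- .sw_align(aa_encode(piece), aa_encode(aa_o), B62o,
                          gap_open = 12, gap_ext = 1, xdrop = 12)
          if (al$score <= 0) next
          qcov <- al$q_end - al$q_start + 1L
          if (qcov >= 0.7 * nchar(piece) && al$score >= 3 * qcov &&
              !grepl("*", substr(aa_o, al$s_start, al$s_end),
                     fixed = TRUE)) {
            clean_hit <- TRUE
            break
          }
        }
        if (clean_hit) next
      }
      ncod <- min(nchar(R) %/% 3L, qgap + 8L)
      if (sh <= st) {
        # skipped content abuts the upstream exon: continue its frame
        cont <- translate_dna(Biostrings::DNAString(substr(R, 1L, 3L * ncod)))
      } else {
        # skipped content abuts the downstream exon: read the frame that
        # runs flush into it
        o <- nchar(R) %% 3L
        cont <- translate_dna(Biostrings::DNAString(
          substr(R, max(1L, nchar(R) - 3L * ncod + 1L - o), nchar(R) - o)))
      }
      if (grepl("*", cont, fixed = TRUE)) {
        extra_stop_at <- c(extra_stop_at, at)
      } else {
        extra_fs_at <- c(extra_fs_at, at)
      }
    }
  }

  # cut the terminal exon at its first in-frame stop so read-through into
  # 3' flanking sequence never masquerades as a premature stop
  aa_last <- translate_dna(genome_subseq(genome, locus$scaffold_id,
                                         exons[last, 1], exons[last, 2],
                                         strand))
  st <- regexpr("*", aa_last, fixed = TRUE)
  if (st > 0L && st < nchar(aa_last)) {
    if (strand == "+") exons[last, 2] <- exons[last, 1] + 3L * st - 1L
    else exons[last, 1] <- exons[last, 2] - 3L * st + 1L
  }

  ext <- c(min(exons[, 1]), max(exons[, 2]))
  if (ext[1] <= 60L || slen - ext[2] <= 60L) clipped <- TRUE

  if (is.null(id)) id <- sprintf("locus%03d", locus$locus_id)
  build_model_from_exons(id, family, locus$scaffold_id, strand, exons,
                         genome, config, ref_query = locus$ref_query,
                         clipped = clipped, extra_fs_at = extra_fs_at,
                         extra_stop_at = extra_stop_at)
}

# Internal: assemble a gene_model from exon coordinates, translating and
# scoring disruptions along the way. Exons must already be in
# transcription order.
build_model_from_exons <- function(id, family, scaffold_id, strand, exons,
                                   genome, config, ref_query = NULL,
                                   clipped = FALSE, extra_fs_at = integer(),
                                   extra_stop_at = integer()) {
  aa <- vapply(seq_len(nrow(exons)), function(k) {
    translate_dna(genome_subseq(genome, scaffold_id, exons[k, 1],
                                exons[k, 2], strand))
  }, character(1))
  full <- paste(aa, collapse = "")
  naa <- nchar(full)
  # disruptions at near-adjacent segment breaks: a gap shorter than an
  # intron that is not a codon multiple is a frameshift; an in-frame
  # short gap hides the codons the aligner skipped -- translate them and
  # count any stop they contain (that is where a premature stop codon
  # lands when it splits an HSP in two)
  fs_at <- integer()
  gapstop_at <- integer()
  gap_stops <- 0L
  if (nrow(exons) > 1L) {
    for (k in 2:nrow(exons)) {
      gap <- if (strand == "+") exons[k, 1] - exons[k - 1L, 2] - 1L
             else exons[k - 1L, 1] - exons[k, 2] - 1L
      if (gap < config$min_intron_nt && gap %% 3L != 0L) {
        fs_at <- c(fs_at, sum(nchar(aa[seq_len(k - 1L)])))
      } else if (gap >= 3L && gap < config$min_intron_nt) {
        gseq <- if (strand == "+") {
          genome_subseq(genome, scaffold_id, exons[k - 1L, 2] + 1L,
                        exons[k, 1] - 1L, strand)
        } else {
          genome_subseq(genome, scaffold_id, exons[k, 2] + 1L,
                        exons[k - 1L, 1] - 1L, strand)
        }
        gaa <- translate_dna(gseq)
        n_st <- sum(strsplit(gaa, "")[[1]] == "*")
        if (n_st > 0L) {
          gap_stops <- gap_stops + n_st
          gapstop_at <- c(gapstop_at, sum(nchar(aa[seq_len(k - 1L)])))
        }
      }
    }
  }
  stop_at <- which(strsplit(full, "")[[1]] == "*")
  premature <- setdiff(stop_at, naa)
  fs_at <- c(fs_at, extra_fs_at)
  gapstop_at <- c(gapstop_at, extra_stop_at)
  gap_stops <- gap_stops + length(extra_stop_at)
  # longest ORF segment free of disruptions
  cuts <- sort(unique(c(0L, premature, fs_at, gapstop_at, naa)))
  seg_len <- diff(cuts)
  best <- which.max(seg_len)
  orf <- substr(full, cuts[best] + 1L, cuts[best + 1L])
  orf <- gsub("\\*$", "", orf)
  gene_model(
    id = id, family = family, scaffold_id = scaffold_id, strand = strand,
    exons = exons, translation = orf,
    disruptions = c(frameshift = length(fs_at),
                    premature_stop = length(premature) + gap_stops),
    status = NA_character_, full_translation = full,
    ref_query = ref_query, clipped = clipped)
}

#' Drop the shortest quartile of predictions
#'
#' Within each family, models are sorted by ascending ORF length and the
#' first `floor(orf_filter_fraction * N)` are removed; models tied with
#' the shortest retained length are all retained.
#'
#' @param models list of [gene_model()] objects.
#' @param config a [pipeline_config()].
#' @return The retained models, in input order.
#' @export
filter_predictions <- function(models, config = pipeline_config()) {
  if (length(models) == 0L) return(models)
  fam <- vapply(models, function(m) m$family, character(1))
  len <- vapply(models, function(m) m$orf_length_aa, numeric(1))
  drop <- logical(length(models))
  for (f in unique(fam)) {
    ix <- which(fam == f)
    r <- floor(config$orf_filter_fraction * length(ix))
    if (r == 0L) next
    o <- ix[order(len[ix])]
    cut_len <- len[o[r + 1L]]
    cand <- o[seq_len(r)]
    drop[cand[len[cand] < cut_len]] <- TRUE
  }
  models[!drop]
}

#' Iterative homology-based annotation
#'
#' Runs the full discovery loop: search (or ingest) HSPs, filter, chain,
#' merge into loci, predict one model per locus, drop the shortest length
#' quartile per family, then feed the surviving predictions back into the
#' query set and repeat. Iteration stops when the locus set -- compared by
#' scaffold, strand and reciprocal extent overlap of at least 50% of the
#' shorter locus -- is unchanged between consecutive rounds, or at
#' `max_iterations` with a warning.
#'
#' @param genome a `genome`.
#' @param queries named character vector / `AAStringSet` of seed protein
#'   queries.
#' @param hsp_source function mapping a named query vector to an
#'   [hsp_table()]; defaults to [builtin_hsp_source()] on `genome`.
#' @param config a [pipeline_config()].
#' @param family family label attached to predictions (also scopes the ORF
#'   length filter). A named list mapping query prefix regexes to families
#'   may be given; the reference query decides each model's family.
#' @return A list with `models` (the reported set, after the per-family
#'   ORF length filter), `models_unfiltered` (every final-round locus
#'   model, fragments included -- the set to use for repertoire-wide
#'   statistics such as tandem clustering), `loci`, per-round `log` and a
#'   `converged` flag.
#' @export
run_iterative_pipeline <- function(genome, queries,
                                   hsp_source = NULL,
                                   config = pipeline_config(),
                                   family = "other") {
  if (methods::is(queries, "AAStringSet")) {
    queries <- stats::setNames(as.character(queries), names(queries))
  }
  if (is.null(hsp_source)) hsp_source <- builtin_hsp_source(genome)
  fam_map <- new.env(parent = emptyenv())
  seed_family <- function(qid) {
    if (!is.list(family)) return(family)
    for (f in names(family)) if (grepl(family[[f]], qid)) return(f)
    "other"
  }
  for (qn in names(queries)) assign(qn, seed_family(qn), envir = fam_map)
  family_of <- function(qid) {
    if (exists(qid, envir = fam_map, inherits = FALSE)) {
      get(qid, envir = fam_map)
    } else seed_family(qid)
  }
  loci_equal <- function(a, b) {
    if (nrow(a) != nrow(b)) return(FALSE)
    if (nrow(a) == 0L) return(TRUE)
    matched <- vapply(seq_len(nrow(a)), function(i) {
      j <- b$scaffold_id == a$scaffold_id[i] & b$strand == a$strand[i]
      if (!any(j)) return(FALSE)
      ov <- pmin(b$end[j], a$end[i]) - pmax(b$start[j], a$start[i]) + 1L
      shorter <- pmin(b$end[j] - b$start[j] + 1L, a$end[i] - a$start[i] + 1L)
      any(ov >= 0.5 * shorter)
    }, logical(1))
    all(matched)
  }
  qset <- queries
  log <- list()
  prev_loci <- NULL
  prev_models <- NULL
  models <- list()
  loci <- NULL
  converged <- FALSE
  for (round in seq_len(config$max_iterations)) {
    if (length(qset) == 0L) {
      log[[round]] <- data.table::data.table(
        round = round, n_queries = 0L, n_hsps = 0L, n_loci = 0L,
        n_models = 0L)
      converged <- TRUE
      loci <- merge_chains_to_loci(chain_hsps(hsp_table(), config),
                                   config, genome)$loci
      break
    }
    hsps <- hsp_source(qset)
    hsps <- filter_hsps(hsps, config)
    chained <- chain_hsps(hsps, config)
    ml <- merge_chains_to_loci(chained, config, genome)
    loci <- ml$loci
    models <- vector("list", nrow(loci))
    for (i in seq_len(nrow(loci))) {
      lr <- loci[i, ]
      models[[i]] <- predict_gene(
        lr, ml$hsps[ml$hsps$locus_id == lr$locus_id, ], genome, config,
        id = sprintf("r%d_locus%03d", round, lr$locus_id),
        family = family_of(lr$ref_query),
        query_seq = qset[[lr$ref_query]])
    }
    # disruption evidence accumulates across rounds: once a round has seen
    # a frameshift or premature stop at a locus, later rounds (whose
    # reference query may be a clean prediction that no longer spans the
    # broken piece) keep that evidence
    if (!is.null(prev_models)) {
      pt <- models_to_table(prev_models)
      for (i in seq_along(models)) {
        ex <- model_extent(models[[i]])
        j <- which(pt$scaffold_id == models[[i]]$scaffold_id &
                     pt$strand == models[[i]]$strand &
                     pmin(pt$end, ex[2]) - pmax(pt$start, ex[1]) + 1L >=
                       0.5 * pmin(pt$end - pt$start + 1L, ex[2] - ex[1] + 1L))
        if (length(j) == 1L) {
          models[[i]]$disruptions <- pmax(models[[i]]$disruptions,
                                          prev_models[[j]]$disruptions)
        }
      }
    }
    models_all <- models
    models <- filter_predictions(models, config)
    for (m in models) assign(m$id, m$family, envir = fam_map)
    log[[round]] <- data.table::data.table(
      round = round, n_queries = length(qset), n_hsps = nrow(hsps),
      n_loci = nrow(loci), n_models = length(models))
    if (!is.null(prev_loci) && loci_equal(loci, prev_loci)) {
      converged <- TRUE
      break
    }
    prev_loci <- loci
    prev_models <- models
    new_q <- stats::setNames(
      vapply(models, function(m) m$translation, character(1)),
      vapply(models, function(m) m$id, character(1)))
    new_q <- new_q[nchar(new_q) >= 30L]
    qset <- c(queries, new_q)
  }
  if (!converged) {
    warning("pipeline did not converge within max_iterations", call. = FALSE)
  }
  if (!exists("models_all", inherits = FALSE)) models_all <- models
  list(models = models, models_unfiltered = models_all, loci = loci,
       log = data.table::rbindlist(log), converged = converged)
}
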