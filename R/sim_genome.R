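# Synthetic genomes with planted chemosensory-receptor-like genes:
# multi-exon genes (including a 9-exon architecture) in tandem arrays,
# pseudogenes carrying frameshifts / premature stops, and models truncated
# by scaffold edges or N-runs, with full ground truth emitted alongside.

#' Specification for a simulated genome
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length_nt length of each scaffold.
#' @param n_intact_genes,n_pseudogenes,n_edge_truncated planted gene
#'   counts per status.
#' @param exon_count_distribution data.frame with columns `k`
#'   (exon count; must offer a 9-exon option) and `p` (probabilities
#'   summing to 1).
#' @param exon_length_aa two-element range of per-exon lengths (aa); exon
#'   draws are redrawn until a gene's protein reaches at least
#'   `min_protein_aa`.
#' @param min_protein_aa minimum planted protein length (default 310, so
#'   intact genes clear a 300-aa cutoff).
#' @param tandem_cluster_sizes sizes of planted same-family tandem
#'   arrays: a named list (per family) or a plain integer vector
#'   (families chosen as genes allow); remaining genes are placed as
#'   singletons. The defaults emulate the published genomic organisation:
#'   about 75% of odorant-receptor genes sit in arrays of 4 or more,
#'   while about half the gustatory receptors have at least one
#'   neighbouring homolog (pairs).
#' @param family_labels families to plant; queries/ancestors are
#'   allocated per family.
#' @param ancestors_per_family number of ancestral query proteins per
#'   family.
#' @param substitution_rate per-site amino-acid divergence of each
#'   planted gene from its family ancestor.
#' @param disruption_rate disruptions per pseudogene (>= 1).
#' @param intron_length_nt range of intron lengths.
#' @param cluster_gene_gap_nt range of end-to-start gaps inside a tandem
#'   array (the lower bound must exceed the HSP chaining gap so
#'   neighbouring genes are never chained).
#' @param block_gap_nt range of gaps between arrays/singletons.
#' @param gc intergenic GC content.
#' @param seed integer seed.
#' @return Object of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_scaffolds = 12L, scaffold_length_nt = 300000L,
                            n_intact_genes = 60L, n_pseudogenes = 15L,
                            n_edge_truncated = 10L,
                            exon_count_distribution =
                              data.frame(k = c(3L, 5L, 7L, 9L),
                                         p = c(0.2, 0.3, 0.2, 0.3)),
                            exon_length_aa = c(40L, 70L),
                            min_protein_aa = 310L,
                            tandem_cluster_sizes = list(
                              OR = c(12L, 9L, 7L, 6L, 5L, 4L),
                              GR = rep(2L, 7L)),
                            family_labels = c("OR", "GR"),
                            ancestors_per_family = c(4L, 2L),
                            substitution_rate = 0.1,
                            disruption_rate = 2L,
                            intron_length_nt = c(200L, 800L),
                            cluster_gene_gap_nt = c(3500L, 7000L),
                            block_gap_nt = c(25000L, 45000L),
                            gc = 0.4, seed = 1L) {
  stopifnot(n_scaffolds >= 1L, scaffold_length_nt > 1000L,
            n_intact_genes >= 0L, n_pseudogenes >= 0L,
            n_edge_truncated >= 0L, disruption_rate >= 1L,
            abs(sum(exon_count_distribution$p) - 1) < 1e-9,
            9L %in% exon_count_distribution$k,
            length(family_labels) == length(ancestors_per_family))
  structure(as.list(environment()), class = "genome_sim_spec")
}

# Internal: random protein (starts with M), random DNA, reverse translation.
random_protein <- function(len) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  paste0("M", paste(sample(aa, len - 1L, replace = TRUE), collapse = ""))
}

random_dna <- function(len, gc = 0.4) {
  if (len <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

mutate_protein <- function(protein, rate) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  v <- strsplit(protein, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  hit <- hit[hit > 1L]                       # keep the start methionine
  for (i in hit) v[i] <- sample(setdiff(aa, v[i]), 1L)
  paste(v, collapse = "")
}

reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  vapply(strsplit(protein, "")[[1]],
         function(a) sample(by_aa[[a]], 1L), character(1),
         USE.NAMES = FALSE)
}

# Internal: is a planted pseudogene's disruption visible? Translating
# each exon in its own frame must hit a stop within the first 300
# cumulative aa (a frameshift whose garbage tail happens to be stop-free
# and confined to the end of one exon would otherwise be undetectable by
# any annotation method, and the gene would not be a credible pseudogene).
pseudogene_visible <- function(g, before_aa = 300L) {
  gc <- Biostrings::GENETIC_CODE
  cum <- 0L
  for (e in seq_len(nrow(g$exons))) {
    s <- substr(g$seq, g$exons[e, 1], g$exons[e, 2])
    n <- nchar(s) %/% 3L
    cods <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- unname(gc[cods])
    aa[is.na(aa)] <- "X"
    if (e == nrow(g$exons)) aa <- aa[-length(aa)]   # terminal stop
    hit <- which(aa == "*")
    if (length(hit) > 0L && cum + hit[1] <= before_aa) return(TRUE)
    cum <- cum + n
  }
  FALSE
}

# Internal: build one gene in transcription space.
# Returns list(seq, exons_local (matrix, transcription order), protein,
# disruptions applied).
build_gene_seq <- function(protein, n_exons, spec, disrupt = 0L,
                           keep_fraction = 1) {
  codons <- c(reverse_translate(protein), sample(c("TAA", "TGA", "TAG"), 1L))
  n_cod <- length(codons)
  first_dis <- NA_integer_
  if (disrupt > 0L) {
    hi <- max(32L, min(280L, n_cod - 10L))
    pos <- sort(sample(31L:hi, disrupt, replace = FALSE))
    for (p in rev(pos)) {
      if (stats::runif(1L) < 0.5) {
        codons[p] <- "TAA"                                  # premature stop
      } else {
        codons[p] <- paste0(codons[p], sample(c("A","C","G","T"), 1L))  # +1 frameshift
      }
    }
    first_dis <- pos[1]
  }
  # split codons into exons of at least ~20 aa, redrawing tiny tails
  repeat {
    lens <- sample(spec$exon_length_aa[1]:spec$exon_length_aa[2],
                   n_exons, replace = TRUE)
    if (n_exons == 1L) { lens <- n_cod; break }
    lens <- round(lens / sum(lens) * n_cod)
    lens[n_exons] <- n_cod - sum(lens[-n_exons])
    if (all(lens >= 15L)) break
  }
  cuts <- cumsum(lens)
  starts <- c(1L, utils::head(cuts, -1L) + 1L)
  parts <- character(0)
  exons <- matrix(0L, nrow = 0L, ncol = 2L)
  pos <- 0L
  for (e in seq_len(n_exons)) {
    ex_seq <- paste(codons[starts[e]:cuts[e]], collapse = "")
    exons <- rbind(exons, c(pos + 1L, pos + nchar(ex_seq)))
    parts <- c(parts, ex_seq)
    pos <- pos + nchar(ex_seq)
    if (e < n_exons) {
      il <- sample(spec$intron_length_nt[1]:spec$intron_length_nt[2], 1L)
      intron <- paste0("GT", random_dna(il - 4L, spec$gc), "AG")
      parts <- c(parts, intron)
      pos <- pos + nchar(intron)
    }
  }
  seqs <- paste(parts, collapse = "")
  if (keep_fraction < 1) {
    # keep the 5' exons, capped so the kept coding stays well short of an
    # intact-length ORF (the fragment must classify as truncated, not intact)
    aa_cum <- cumsum(exons[, 2] - exons[, 1] + 1L) %/% 3L
    keep_ex <- max(1L, min(nrow(exons) - 1L, sum(aa_cum <= 260L)))
    cut_at <- exons[keep_ex, 2]
    seqs <- substr(seqs, 1L, cut_at)
    exons <- exons[seq_len(keep_ex), , drop = FALSE]
    protein <- substr(protein, 1L,
                      sum(exons[, 2] - exons[, 1] + 1L) %/% 3L)
  }
  list(seq = seqs, exons = exons, protein = protein, first_dis = first_dis)
}

#' Simulate a genome with planted receptor genes
#'
#' Generates scaffolds of random intergenic sequence into which intact
#' genes, pseudogenes and edge-truncated gene fragments are planted, in
#' tandem arrays and as singletons, together with the full ground truth.
#' Each planted gene derives from one of a small set of per-family
#' ancestor proteins (emitted as the query set), diverged by point
#' substitutions. Intact genes have uninterrupted spliced ORFs of at
#' least `min_protein_aa`; pseudogenes carry `disruption_rate` frameshift
#' or premature-stop disruptions, the first before codon 280; edge
#' fragments keep roughly half of their exons and are cut either by the
#' scaffold end or by an inserted run of 300 N.
#'
#' @param spec a [genome_sim_spec()].
#' @return List with `genome` (a `genome`), `queries` (named character,
#'   the family ancestors), and `truth` (list: `genes` table, `exons`
#'   table, `clusters` table).
#' @export
simulate_genome <- function(spec = genome_sim_spec()) {
  with_seed(spec$seed, {
    fams <- rep(spec$family_labels, spec$ancestors_per_family)
    anc_names <- unlist(lapply(seq_along(spec$family_labels), function(i) {
      sprintf("%s_anc%d", spec$family_labels[i],
              seq_len(spec$ancestors_per_family[i]))
    }))
    ancestors <- stats::setNames(
      vapply(fams, function(f) random_protein(480L), character(1)),
      anc_names)
    anc_family <- stats::setNames(fams, anc_names)

    n_total <- spec$n_intact_genes + spec$n_pseudogenes + spec$n_edge_truncated
    status <- sample(c(rep("intact", spec$n_intact_genes),
                       rep("pseudogene", spec$n_pseudogenes),
                       rep("partial_assembly", spec$n_edge_truncated)))
    # family sizes proportional to the ancestors available
    fam_counts <- round(n_total * spec$ancestors_per_family /
                          sum(spec$ancestors_per_family))
    fam_counts[1] <- n_total - sum(fam_counts[-1])
    fam_of_gene <- sample(rep(spec$family_labels, fam_counts))

    # tandem arrays are same-family blocks; the rest are singletons.
    # Scaffold-end fragments are placed at scaffold boundaries, so they
    # are kept out of the arrays to preserve the planted array sizes.
    cluster_plan <- if (is.list(spec$tandem_cluster_sizes)) {
      spec$tandem_cluster_sizes
    } else {
      list(any = spec$tandem_cluster_sizes)
    }
    edge_pool <- which(status == "partial_assembly")
    end_frag_ids <- edge_pool[seq_len(floor(length(edge_pool) / 2))]
    blocks <- list()
    used <- logical(n_total)
    for (f in names(cluster_plan)) {
      for (cs in cluster_plan[[f]]) {
        fams <- if (f == "any") sample(spec$family_labels) else f
        for (ff in fams) {
          free <- which(!used & fam_of_gene == ff &
                          !(seq_len(n_total) %in% end_frag_ids))
          if (length(free) >= cs) {
            sel <- free[seq_len(cs)]
            used[sel] <- TRUE
            blocks[[length(blocks) + 1L]] <- sel
            break
          }
        }
      }
    }
    for (i in which(!used)) blocks[[length(blocks) + 1L]] <- i
    blocks <- sample(blocks)

    # construct gene sequences
    genes <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      anc <- sample(names(anc_family)[anc_family == fam_of_gene[i]], 1L)
      repeat {
        k <- sample(spec$exon_count_distribution$k, 1L,
                    prob = spec$exon_count_distribution$p)
        lens <- sample(spec$exon_length_aa[1]:spec$exon_length_aa[2], k,
                       replace = TRUE)
        if (sum(lens) >= spec$min_protein_aa) break
      }
      L <- min(sum(lens), nchar(ancestors[[anc]]))
      prot <- mutate_protein(substr(ancestors[[anc]], 1L, L),
                             spec$substitution_rate)
      st <- status[i]
      tries <- 0L
      repeat {
        g <- build_gene_seq(
          prot, k, spec,
          disrupt = if (st == "pseudogene") spec$disruption_rate else 0L,
          keep_fraction = if (st == "partial_assembly") 0.5 else 1)
        if (st != "pseudogene" || pseudogene_visible(g)) break
        tries <- tries + 1L
        if (tries > 20L) break
      }
      g$id <- sprintf("%s_g%03d", fam_of_gene[i], i)
      g$family <- fam_of_gene[i]
      g$status <- st
      g$ancestor <- anc
      g$strand <- sample(c("+", "-"), 1L)
      genes[[i]] <- g
    }

    # edge fragments: half end at a scaffold boundary, half abut an N-run
    edge_ids <- which(status == "partial_assembly")
    scaffold_end_ids <- edge_ids[seq_len(floor(length(edge_ids) / 2))]
    for (i in scaffold_end_ids) genes[[i]]$strand <- "+"

    # lay blocks onto scaffolds
    sc_parts <- rep(list(character()), spec$n_scaffolds)
    sc_cursor <- rep(0L, spec$n_scaffolds)
    placements <- list()
    sc <- 1L
    reserve_tail <- 9000L   # room for end-of-scaffold fragments + padding
    for (b in blocks) {
      b_edge_end <- b[b %in% scaffold_end_ids]
      b_norm <- setdiff(b, scaffold_end_ids)
      if (length(b_norm) > 0L) {
        block_len <- sum(vapply(b_norm, function(i) {
          nchar(genes[[i]]$seq) +
            (if (genes[[i]]$status == "partial_assembly") 300L else 0L)
        }, numeric(1))) +
          (length(b_norm) - 1L) * spec$cluster_gene_gap_nt[2] +
          spec$block_gap_nt[2]
        tries <- 0L
        while (sc_cursor[sc] + block_len >
               spec$scaffold_length_nt - reserve_tail) {
          sc <- sc %% spec$n_scaffolds + 1L
          tries <- tries + 1L
          if (tries > spec$n_scaffolds) {
            stop("requested genes do not fit on the scaffolds", call. = FALSE)
          }
        }
        gap <- sample(spec$block_gap_nt[1]:spec$block_gap_nt[2], 1L)
        sc_parts[[sc]] <- c(sc_parts[[sc]], random_dna(gap, spec$gc))
        sc_cursor[sc] <- sc_cursor[sc] + gap
        for (j in seq_along(b_norm)) {
          i <- b_norm[j]
          g <- genes[[i]]
          gene_seq <- g$seq
          npad <- 0L
          if (g$status == "partial_assembly") {
            npad <- 300L
            gene_seq <- paste0(gene_seq, strrep("N", npad))
          }
          emitted <- if (g$strand == "+") gene_seq else
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(gene_seq)))
          placements[[length(placements) + 1L]] <- list(
            idx = i, scaffold = sc, offset = sc_cursor[sc],
            emitted_len = nchar(emitted), npad = npad,
            cluster_block = length(b) > 1L,
            block_key = paste0("b", match(list(b), blocks)))
          sc_parts[[sc]] <- c(sc_parts[[sc]], emitted)
          sc_cursor[sc] <- sc_cursor[sc] + nchar(emitted)
          if (j < length(b_norm)) {
            gp <- sample(spec$cluster_gene_gap_nt[1]:
                           spec$cluster_gene_gap_nt[2], 1L)
            sc_parts[[sc]] <- c(sc_parts[[sc]], random_dna(gp, spec$gc))
            sc_cursor[sc] <- sc_cursor[sc] + gp
          }
        }
      }
      for (i in b_edge_end) {
        placements[[length(placements) + 1L]] <- list(
          idx = i, scaffold = NA_integer_, offset = NA_integer_,
          emitted_len = nchar(genes[[i]]$seq), npad = 0L,
          cluster_block = FALSE, block_key = NA_character_)
      }
    }

    # pad scaffolds; append scaffold-end fragments flush with the end
    end_frags <- Filter(function(p) is.na(p$scaffold), placements)
    if (length(end_frags) > spec$n_scaffolds) {
      stop("more scaffold-end fragments than scaffolds", call. = FALSE)
    }
    scaffolds <- character(spec$n_scaffolds)
    for (s in seq_len(spec$n_scaffolds)) {
      body <- paste(sc_parts[[s]], collapse = "")
      frag <- if (s <= length(end_frags)) end_frags[[s]] else NULL
      frag_len <- if (is.null(frag)) 0L else frag$emitted_len
      pad <- spec$scaffold_length_nt - nchar(body) - frag_len
      if (pad < 0L) stop("requested genes do not fit on the scaffolds",
                         call. = FALSE)
      body <- paste0(body, random_dna(pad, spec$gc))
      if (!is.null(frag)) {
        for (k in seq_along(placements)) {
          if (identical(placements[[k]]$idx, frag$idx)) {
            placements[[k]]$scaffold <- s
            placements[[k]]$offset <- nchar(body)
          }
        }
        body <- paste0(body, genes[[frag$idx]]$seq)
      }
      scaffolds[s] <- body
    }
    names(scaffolds) <- sprintf("scaffold%02d", seq_len(spec$n_scaffolds))
    gn <- genome(scaffolds)

    # ground truth tables
    truth_genes <- list()
    truth_exons <- list()
    for (p in placements) {
      g <- genes[[p$idx]]
      EL <- nchar(g$seq) + p$npad     # emitted length incl. any N-run
      gstart <- p$offset + 1L
      ex <- g$exons
      fwd <- if (g$strand == "+") {
        cbind(gstart + ex[, 1] - 1L, gstart + ex[, 2] - 1L)
      } else {
        cbind(gstart + EL - ex[, 2], gstart + EL - ex[, 1])
      }
      truth_genes[[length(truth_genes) + 1L]] <- data.table::data.table(
        id = g$id, family = g$family, status = g$status,
        scaffold_id = names(scaffolds)[p$scaffold], strand = g$strand,
        start = min(fwd[, 1]), end = max(fwd[, 2]),
        n_exons = nrow(ex), protein = g$protein, ancestor = g$ancestor,
        block = p$block_key, in_cluster = p$cluster_block)
      truth_exons[[length(truth_exons) + 1L]] <- data.table::data.table(
        gene_id = g$id, exon = seq_len(nrow(ex)),
        start = fwd[, 1], end = fwd[, 2])
    }
    tg <- data.table::rbindlist(truth_genes)
    te <- data.table::rbindlist(truth_exons)
    cl <- tg[tg$in_cluster & !is.na(tg$block),
             list(scaffold_id = scaffold_id[1], family = family[1],
                  size = .N, members = paste(id, collapse = ",")),
             by = "block"]
    list(genome = gn, queries = ancestors,
         truth = list(genes = tg, exons = te, clusters = cl))
  })
}
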