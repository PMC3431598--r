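# Shared fixture builders. Everything is generated in code; nothing is
# read from disk.

aa20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

rand_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0("M", paste(sample(aa20, len - 1L, replace = TRUE), collapse = ""))
}

# deterministic reverse translation (first codon of each amino acid)
codon_of <- local({
  gc <- Biostrings::GENETIC_CODE
  by <- vapply(split(names(gc), gc), `[[`, character(1), 1L)
  function(aa) unname(by[aa])
})

protein_to_cds <- function(protein, stop_codon = "TAA") {
  paste0(paste(codon_of(strsplit(protein, "")[[1]]), collapse = ""),
         stop_codon)
}

# Build a tiny genome containing one multi-exon gene with known exon
# coordinates. Returns list(genome, protein, exons (fwd coords,
# transcription order), strand).
plant_gene <- function(protein, n_exons = 2L, strand = "+",
                       intron_len = 120L, pad = 500L, seed = 1L,
                       scaffold_id = "chr1") {
  set.seed(seed)
  cds <- protein_to_cds(protein)
  n_cod <- nchar(cds) / 3L
  cuts <- sort(sample(2:(n_cod - 2L), n_exons - 1L))
  bounds <- c(0L, cuts, n_cod)
  parts <- character(0)
  exons_local <- matrix(0L, 0L, 2L)
  pos <- 0L
  for (e in seq_len(n_exons)) {
    ex <- substr(cds, 3L * bounds[e] + 1L, 3L * bounds[e + 1L])
    exons_local <- rbind(exons_local, c(pos + 1L, pos + nchar(ex)))
    parts <- c(parts, ex)
    pos <- pos + nchar(ex)
    if (e < n_exons) {
      intron <- paste0("GT", paste(sample(c("A","C","G","T"),
                                          intron_len - 4L, replace = TRUE),
                                   collapse = ""), "AG")
      parts <- c(parts, intron)
      pos <- pos + nchar(intron)
    }
  }
  gene_seq <- paste(parts, collapse = "")
  flank <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                             collapse = "")
  if (strand == "-") {
    emitted <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gene_seq)))
  } else {
    emitted <- gene_seq
  }
  scaff <- paste0(flank(pad), emitted, flank(pad))
  Lg <- nchar(gene_seq)
  fwd <- if (strand == "+") {
    cbind(pad + exons_local[, 1], pad + exons_local[, 2])
  } else {
    cbind(pad + Lg - exons_local[, 2] + 1L, pad + Lg - exons_local[, 1] + 1L)
  }
  list(genome = genome(stats::setNames(scaff, scaffold_id)),
       protein = protein, exons = fwd, strand = strand,
       scaffold_id = scaffold_id)
}

# quick hsp row builder
hsp_row <- function(q = "q1", sc = "s1", bit = 100, e = 1e-20,
                    qs = 1L, qe = 10L, ss = 1L, se = 30L, strand = "+",
                    frame = 1L) {
  data.table::data.table(query_id = q, scaffold_id = sc, bit_score = bit,
                         e_value = e, q_start = as.integer(qs),
                         q_end = as.integer(qe), s_start = as.integer(ss),
                         s_end = as.integer(se), strand = strand,
                         frame = as.integer(frame))
}

as_hsp_table <- function(...) {
  h <- data.table::rbindlist(list(...))
  data.table::setattr(h, "class", c("hsp_table", class(h)))
  h[]
}

# six-taxon time tree used across birth-death tests
six_taxon_tree <- function() {
  read_tree(text = "(((A:50,B:50):100,(C:70,D:70):80):100,(E:120,F:120):130);")
}

# independent chaining oracle: connected components over consecutive
# strand-ordered pairs satisfying the three criteria
chain_oracle <- function(hsps, gap_max = 3000L) {
  n <- nrow(hsps)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) parent[find(i)] <<- find(j)
  key <- paste(hsps$query_id, hsps$scaffold_id, hsps$strand)
  for (k in unique(key)) {
    ix <- which(key == k)
    strand <- hsps$strand[ix[1]]
    ord <- if (strand == "+") ix[order(hsps$s_start[ix], hsps$s_end[ix])]
           else ix[order(-hsps$s_end[ix], -hsps$s_start[ix])]
    if (length(ord) < 2L) next
    for (m in 2:length(ord)) {
      a <- ord[m - 1L]; b <- ord[m]
      gap <- if (strand == "+") hsps$s_start[b] - hsps$s_end[a] - 1L
             else hsps$s_start[a] - hsps$s_end[b] - 1L
      if (gap <= gap_max && hsps$q_start[a] < hsps$q_start[b]) union2(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# random HSP set generator for property tests
random_hsps <- function(n, seed) {
  set.seed(seed)
  qs <- sample(1:200, n, replace = TRUE)
  len <- sample(5:60, n, replace = TRUE)
  ss <- sample(1:20000, n, replace = TRUE)
  as_hsp_table(data.table::data.table(
    query_id = sample(c("qA", "qB"), n, replace = TRUE),
    scaffold_id = sample(c("s1", "s2"), n, replace = TRUE),
    bit_score = round(runif(n, 30, 300), 1),
    e_value = 10^runif(n, -40, -6),
    q_start = qs, q_end = qs + len,
    s_start = ss, s_end = ss + 3L * (len + 1L) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    frame = sample(c(1:3, -(1:3)), n, replace = TRUE)))
}

# partition check: same grouping up to relabelling
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# exhaustive duplication-loss oracle over all consistent mappings of a
# binary gene tree into a species tree (family present at species root)
dl_oracle <- function(gene_tree, species_tree, species_pattern) {
  info <- chemoreceptR:::species_tree_info(species_tree)
  sp <- leaf_species(gene_tree$tip.label, species_pattern)
  map_leaf <- match(sp, info$labels)
  ntip <- length(gene_tree$tip.label)
  ch <- chemoreceptR:::tree_children(gene_tree)
  dist_down <- function(top, bot) {
    d <- 0L
    while (bot != top) { bot <- info$parent[bot]; d <- d + 1L }
    d
  }
  anc_or_self <- function(v) chemoreceptR:::sp_ancestors(info, v)
  # gene internal nodes in postorder
  internals <- setdiff(seq_len(ntip + gene_tree$Nnode), seq_len(ntip))
  # recursive enumeration of mappings with cost
  best <- Inf
  rec <- function(node) {
    # returns list of (map, cost) alternatives for subtree
    if (node <= ntip) {
      return(list(list(map = map_leaf[node], cost = 0L)))
    }
    kids <- ch[[node]]
    stopifnot(length(kids) == 2L)
    L <- rec(kids[1]); R <- rec(kids[2])
    out <- list()
    for (l in L) for (r in R) {
      base <- chemoreceptR:::sp_lca(info, l$map, r$map)
      for (m in anc_or_self(base)) {
        dup <- (m == l$map || m == r$map || m != base)
        # event classification given mapping m:
        is_spec <- (m == base) && (m != l$map) && (m != r$map)
        kL <- dist_down(m, l$map); kR <- dist_down(m, r$map)
        loss <- if (is_spec) (kL - 1L) + (kR - 1L) else kL + kR
        dcount <- if (is_spec) 0L else 1L
        out[[length(out) + 1L]] <- list(
          map = m, cost = l$cost + r$cost + dcount + loss)
      }
    }
    # keep the best cost per map value (dominance pruning)
    maps <- vapply(out, `[[`, integer(1), "map")
    costs <- vapply(out, `[[`, numeric(1), "cost")
    keep <- !duplicated(maps) | costs < ave(costs, maps, FUN = min)
    lapply(unique(maps), function(m) {
      list(map = m, cost = min(costs[maps == m]))
    })
  }
  root_alts <- rec(ntip + 1L)
  min(vapply(root_alts, function(a) {
    stem <- dist_down(info$root, a$map)
    a$cost + stem
  }, numeric(1)))
}

# Vectorised Gillespie oracle for the single-branch birth-death process:
# independent of the closed-form transition probabilities it checks.
mc_bd_counts <- function(n0, lambda, mu, t, nreps, seed) {
  set.seed(seed)
  n <- rep(as.integer(n0), nreps)
  tcur <- rep(0, nreps)
  active <- n > 0L
  while (any(active)) {
    idx <- which(active)
    dt <- stats::rexp(length(idx), n[idx] * (lambda + mu))
    tcur[idx] <- tcur[idx] + dt
    done <- tcur[idx] > t
    idx2 <- idx[!done]
    active[idx[done]] <- FALSE
    if (length(idx2) > 0L) {
      birth <- stats::runif(length(idx2)) < lambda / (lambda + mu)
      n[idx2] <- n[idx2] + ifelse(birth, 1L, -1L)
      active[idx2[n[idx2] == 0L]] <- FALSE
    }
  }
  n
}

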