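# Duplication-loss reconciliation of (possibly multifurcating) gene trees
# against a rooted species tree, with event counts attributed to species
# branches and ancestral copy numbers derived from them.

# Internal: species-tree bookkeeping (parent, depth, children, lca).
species_tree_info <- function(species_tree) {
  ntip <- length(species_tree$tip.label)
  n <- ntip + species_tree$Nnode
  parent <- rep(NA_integer_, n)
  for (i in seq_len(nrow(species_tree$edge))) {
    parent[species_tree$edge[i, 2]] <- species_tree$edge[i, 1]
  }
  root <- ntip + 1L
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  repeat {
    todo <- which(is.na(depth) & !is.na(parent) & !is.na(depth[parent]))
    if (length(todo) == 0L) break
    depth[todo] <- depth[parent[todo]] + 1L
  }
  list(ntip = ntip, n = n, parent = parent, depth = depth, root = root,
       children = tree_children(species_tree),
       labels = species_tree$tip.label)
}

sp_ancestors <- function(info, v) {
  out <- v
  while (!is.na(info$parent[v])) {
    v <- info$parent[v]
    out <- c(out, v)
  }
  out
}

sp_lca <- function(info, a, b) {
  if (a == b) return(a)
  aa <- sp_ancestors(info, a)
  bb <- sp_ancestors(info, b)
  intersect(aa, bb)[1]
}

# Internal: path root-ward node sequence from ancestor `top` down to `bot`.
sp_path_down <- function(info, top, bot) {
  path <- bot
  while (bot != top) {
    bot <- info$parent[bot]
    path <- c(bot, path)
  }
  path
}

# Internal: convert a phylo gene tree into nested lists of species ids.
gene_tree_nested <- function(gene_tree, info, species_pattern) {
  sp <- leaf_species(gene_tree$tip.label, species_pattern)
  map <- match(sp, info$labels)
  if (anyNA(map)) {
    stop("gene-tree leaf species not found in species tree: ",
         paste(unique(gene_tree$tip.label[is.na(map)]), collapse = ", "),
         call. = FALSE)
  }
  ch <- tree_children(gene_tree)
  ntip <- length(gene_tree$tip.label)
  rec <- function(v) {
    if (v <= ntip) return(list(leaf = map[v], label = gene_tree$tip.label[v]))
    list(children = lapply(ch[[v]], rec))
  }
  rec(ntip + 1L)
}

# Internal: cost and attribution of losses for one gene edge whose parent
# maps to `m` (dup status given) and child maps to `mc`.
edge_losses <- function(info, m, mc, parent_is_dup) {
  if (m == mc && !parent_is_dup) return(integer())   # no descent
  path <- sp_path_down(info, m, mc)
  k <- length(path) - 1L
  loss_nodes <- integer()
  from <- if (parent_is_dup) 1L else 2L   # dup lineages pass the speciation at m
  if (k >= from) {
    for (i in from:k) {
      s <- path[i]
      onpath <- path[i + 1L]
      loss_nodes <- c(loss_nodes, setdiff(info$children[[s]], onpath))
    }
  }
  loss_nodes
}

# Internal: combine two resolved subtrees at a binary gene node.
# Each subtree is list(map, gains, losses, total); vectors indexed by
# species node id.
combine_two <- function(info, L, R) {
  m <- sp_lca(info, L$map, R$map)
  dup <- (m == L$map || m == R$map)
  gains <- L$gains + R$gains
  losses <- L$losses + R$losses
  if (dup) gains[m] <- gains[m] + 1L
  for (side in list(L, R)) {
    ln <- edge_losses(info, m, side$map, dup)
    for (s in ln) losses[s] <- losses[s] + 1L
  }
  list(map = m, gains = gains, losses = losses,
       total = sum(gains) + sum(losses))
}

# Internal: all rooted binary topologies over k items, as nested pair
# structures (lists of item indices).
binary_topologies <- function(k) {
  trees <- list(1L)
  for (i in 2:k) {
    nxt <- list()
    for (tr in trees) {
      spots <- attach_points(tr)
      for (s in seq_len(spots)) {
        nxt[[length(nxt) + 1L]] <- attach_at(tr, s, i)
      }
    }
    trees <- nxt
  }
  trees
}

attach_points <- function(tr) {
  if (!is.list(tr)) return(1L)
  1L + attach_points(tr[[1]]) + attach_points(tr[[2]])
}

attach_at <- function(tr, s, leaf) {
  if (s == 1L) return(list(tr, leaf))
  s <- s - 1L
  nl <- attach_points(tr[[1]])
  if (s <= nl) list(attach_at(tr[[1]], s, leaf), tr[[2]])
  else list(tr[[1]], attach_at(tr[[2]], s - nl, leaf))
}

# Internal: evaluate a nested pair structure over child subtree results.
eval_topology <- function(info, tr, parts) {
  if (!is.list(tr)) return(parts[[tr]])
  combine_two(info,
              eval_topology(info, tr[[1]], parts),
              eval_topology(info, tr[[2]], parts))
}

# Internal: resolve a polytomy over resolved child parts; exhaustive for
# <= max_exhaustive children, greedy pairwise agglomeration above.
resolve_polytomy <- function(info, parts, max_exhaustive = 7L) {
  k <- length(parts)
  if (k == 1L) return(parts[[1]])
  if (k == 2L) return(combine_two(info, parts[[1]], parts[[2]]))
  if (k <= max_exhaustive) {
    best <- NULL
    for (tr in binary_topologies(k)) {
      cand <- eval_topology(info, tr, parts)
      if (is.null(best) || cand$total < best$total) best <- cand
    }
    return(best)
  }
  while (length(parts) > 1L) {
    bi <- bj <- 1L
    best <- NULL
    for (i in 1:(length(parts) - 1L)) {
      for (j in (i + 1L):length(parts)) {
        cand <- combine_two(info, parts[[i]], parts[[j]])
        if (is.null(best) || cand$total < best$total) {
          best <- cand; bi <- i; bj <- j
        }
      }
    }
    parts[[bi]] <- best
    parts[[bj]] <- NULL
  }
  parts[[1]]
}

#' Duplication-loss reconciliation of a gene tree
#'
#' Embeds a rooted gene tree into a rooted species tree by LCA mapping and
#' counts the minimal duplication and loss events, attributing each to a
#' species-tree branch. Polytomies (e.g. produced by
#' [collapse_low_support()]) are resolved into the binary refinement
#' minimising duplications + losses -- exhaustively for polytomies of up
#' to 7 children, by greedy pairwise agglomeration above that. The family
#' is taken to be present (single copy) at the species-tree root, so a
#' gene tree missing a species entirely implies losses on the missing
#' lineages.
#'
#' @param gene_tree rooted `phylo`; leaf names carry species prefixes.
#' @param species_tree rooted `phylo` whose tip labels are the species
#'   codes.
#' @param species_pattern regex extracting the species code from gene
#'   leaf names.
#' @return A list of class `reconciliation`: `duplications`, `losses`
#'   (totals), `events` (`data.table` per species branch: gains, losses,
#'   copy number at the branch's child node), and `root_copies`.
#' @export
reconcile_dl <- function(gene_tree, species_tree,
                         species_pattern = "^(Cf|Hs|Lh|Pb|Am|Nv)") {
  info <- species_tree_info(species_tree)
  nested <- gene_tree_nested(gene_tree, info, species_pattern)
  zero <- rep(0L, info$n)
  rec <- function(node) {
    if (!is.null(node$leaf)) {
      return(list(map = node$leaf, gains = zero, losses = zero, total = 0L))
    }
    parts <- lapply(node$children, rec)
    resolve_polytomy(info, parts)
  }
  res <- rec(nested)
  # virtual stem above the gene root: family originates at the species root
  gains <- res$gains
  losses <- res$losses
  for (s in edge_losses(info, info$root, res$map, parent_is_dup = TRUE)) {
    losses[s] <- losses[s] + 1L
  }
  copies <- rep(NA_integer_, info$n)
  copies[info$root] <- 1L + gains[info$root] - losses[info$root]
  repeat {
    todo <- which(is.na(copies) & !is.na(info$parent) &
                    !is.na(copies[info$parent]))
    if (length(todo) == 0L) break
    copies[todo] <- copies[info$parent[todo]] + gains[todo] - losses[todo]
  }
  ev <- data.table::data.table(
    node = seq_len(info$n),
    label = c(info$labels, rep("", info$n - info$ntip)),
    is_tip = seq_len(info$n) <= info$ntip,
    gains = gains, losses = losses, copies = copies)
  structure(list(duplications = sum(gains), losses = sum(losses),
                 events = ev, root_copies = copies[info$root]),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation> %d duplication(s), %d loss(es), root copies %d\n",
              x$duplications, x$losses, x$root_copies))
  invisible(x)
}

#' Minimum-change parsimony on family counts
#'
#' Sankoff dynamic programming with unit cost per copy gained or lost,
#' giving the minimal total number of gain/loss events able to explain the
#' observed per-species counts on the species tree, plus one optimal
#' ancestral count assignment (ties resolved toward smaller counts).
#'
#' @param counts named integer vector of per-species gene counts (names =
#'   species-tree tip labels).
#' @param species_tree rooted `phylo`.
#' @return List with `total_events`, `gains`, `losses` and `ancestral`
#'   (counts per node; tips first, in `phylo` node order).
#' @export
parsimony_events <- function(counts, species_tree) {
  info <- species_tree_info(species_tree)
  obs <- counts[info$labels]
  if (anyNA(obs)) stop("counts must cover every species-tree tip", call. = FALSE)
  cmax <- max(2L, 2L * max(obs))
  states <- 0:cmax
  cost <- matrix(0, nrow = info$n, ncol = cmax + 1L)
  for (i in seq_len(info$ntip)) {
    cost[i, ] <- Inf
    cost[i, obs[i] + 1L] <- 0
  }
  ord <- order(info$depth, decreasing = TRUE)
  for (v in ord) {
    if (v <= info$ntip) next
    for (ci in info$children[[v]]) {
      child_best <- vapply(states, function(c) {
        min(cost[ci, ] + abs(states - c))
      }, numeric(1))
      cost[v, ] <- cost[v, ] + child_best
    }
  }
  assign_ct <- rep(NA_integer_, info$n)
  assign_ct[info$root] <- states[which.min(cost[info$root, ])]
  order_down <- order(info$depth)
  gains <- losses <- 0L
  for (v in order_down) {
    if (v == info$root) next
    p <- info$parent[v]
    tot <- cost[v, ] + abs(states - assign_ct[p])
    assign_ct[v] <- states[which.min(tot)]
    d <- assign_ct[v] - assign_ct[p]
    if (d > 0L) gains <- gains + d else losses <- losses - d
  }
  list(total_events = gains + losses, gains = gains, losses = losses,
       ancestral = assign_ct)
}
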