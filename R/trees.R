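#' Read a rooted, support-labelled newick tree
#'
#' Wraps [ape::read.tree()] with the validation the downstream analyses
#' rely on: the tree must parse, be rooted, and carry unique leaf names.
#' Internal-node labels are interpreted as integer bootstrap supports
#' (0-100); an absent or empty label is stored as `NA` ("unknown") and is
#' treated as below any threshold by [collapse_low_support()].
#'
#' @param path newick file path, or use `text` for a literal string.
#' @param text newick string (overrides `path`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    suppressWarnings(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("newick parse error", call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf names in tree", call. = FALSE)
  }
  # trees are interpreted as rooted exactly as written; a basal polytomy
  # (e.g. after support collapsing) is a rooted multifurcation
  tr
}

#' Bootstrap supports of internal nodes
#'
#' @param tree a `phylo`.
#' @return Integer vector, one element per internal node (in `phylo` node
#'   order), `NA` where the label is missing or non-numeric.
#' @export
node_supports <- function(tree) {
  nn <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_integer_, nn))
  sup <- suppressWarnings(as.integer(lab))
  sup[!is.na(sup) & (sup < 0L | sup > 100L)] <- NA_integer_
  sup
}

#' Species of gene-tree leaves
#'
#' Species are encoded as leaf-name prefixes in the field's usual style
#' (e.g. `CfOr263`, `HsOr55`). The prefix pattern is configurable.
#'
#' @param labels character vector of leaf names.
#' @param pattern regex whose match at the start of a label is the species
#'   code.
#' @return Character vector of species codes (`NA` where no match).
#' @export
leaf_species <- function(labels, pattern = "^(Cf|Hs|Lh|Pb|Am|Nv)") {
  m <- regexpr(pattern, labels)
  out <- rep(NA_character_, length(labels))
  ok <- m > 0L
  out[ok] <- regmatches(labels, m)[seq_len(sum(ok))]
  out
}

# Internal: children list indexed by node id (tips 1..n, root n+1, ...).
tree_children <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

# Internal: tip index sets per node (list over all node ids).
tree_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  ch <- tree_children(tree)
  tips <- vector("list", ntip + tree$Nnode)
  rec <- function(v) {
    if (v <= ntip) return(v)
    r <- unlist(lapply(ch[[v]], rec))
    tips[[v]] <<- r
    r
  }
  rec(ntip + 1L)
  for (i in seq_len(ntip)) tips[[i]] <- i
  tips
}

#' Collapse poorly supported branches
#'
#' Contracts every internal edge whose child node's bootstrap support is
#' strictly below `threshold`, or unknown, producing polytomies. The rule
#' is strict: support exactly equal to the threshold is retained. The leaf
#' set is unchanged; branch lengths of contracted edges are added to their
#' children so leaf depths are preserved when lengths are present.
#'
#' @param tree a rooted `phylo` with supports in `node.label`.
#' @param threshold integer support threshold (default 70).
#' @return A `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold = 70L) {
  ntip <- length(tree$tip.label)
  sup <- node_supports(tree)
  ch <- tree_children(tree)
  has_len <- !is.null(tree$edge.length)
  elen <- stats::setNames(
    if (has_len) tree$edge.length else rep(NA_real_, nrow(tree$edge)),
    tree$edge[, 2])
  root <- ntip + 1L

  rec <- function(node) {
    # returns list of fragments: each list(str, len)
    if (node <= ntip) {
      return(list(list(str = tree$tip.label[node], len = elen[as.character(node)])))
    }
    frags <- unlist(lapply(ch[[node]], rec), recursive = FALSE)
    s <- sup[node - ntip]
    lab <- if (is.na(s)) "" else as.character(s)
    inner <- paste(vapply(frags, function(f) {
      if (has_len && !is.na(f$len)) paste0(f$str, ":", format(f$len, digits = 12))
      else f$str
    }, character(1)), collapse = ",")
    this_len <- if (node == root) NA_real_ else elen[as.character(node)]
    if (node != root && (is.na(s) || s < threshold)) {
      # contract this edge: splice children into the parent
      if (has_len && !is.na(this_len)) {
        frags <- lapply(frags, function(f) {
          f$len <- if (is.na(f$len)) this_len else f$len + this_len
          f
        })
      }
      return(frags)
    }
    list(list(str = paste0("(", inner, ")", lab), len = this_len))
  }

  top <- rec(root)[[1]]
  read_tree(text = paste0(top$str, ";"))
}

#' Single-copy ortholog clades
#'
#' Finds the maximal well-supported clades containing exactly one gene
#' from each species in `species_set` and no gene from any other species
#' -- the pattern of strict 1-to-1 orthology retained across lineages.
#' Returned clades are mutually disjoint (a maximal clade swallows any
#' nested candidate).
#'
#' @param gene_tree rooted `phylo` with supports and species-prefixed leaf
#'   names.
#' @param species_set character vector of required species codes.
#' @param support_threshold minimum bootstrap support of the clade node
#'   (default 70). The root, which has no incoming branch to evaluate, is
#'   admitted when the whole tree forms such a clade.
#' @param species_pattern passed to [leaf_species()].
#' @return List of character vectors (leaf names), one per clade.
#' @export
find_single_copy_clades <- function(gene_tree, species_set,
                                    support_threshold = 70L,
                                    species_pattern = "^(Cf|Hs|Lh|Pb|Am|Nv)") {
  ntip <- length(gene_tree$tip.label)
  sp <- leaf_species(gene_tree$tip.label, species_pattern)
  tips <- tree_clades(gene_tree)
  sup <- node_supports(gene_tree)
  root <- ntip + 1L
  qualifies <- function(v) {
    spv <- sp[tips[[v]]]
    length(spv) == length(species_set) && !anyNA(spv) &&
      setequal(spv, species_set) && !anyDuplicated(spv) &&
      (v == root || (!is.na(sup[v - ntip]) && sup[v - ntip] >= support_threshold))
  }
  out <- list()
  claimed <- logical(ntip)
  # preorder: maximal clades claim their tips first
  ord <- c(root, unique(gene_tree$edge[, 2][gene_tree$edge[, 2] > ntip]))
  for (v in ord) {
    tv <- tips[[v]]
    if (any(claimed[tv])) next
    if (qualifies(v)) {
      out[[length(out) + 1L]] <- gene_tree$tip.label[tv]
      claimed[tv] <- TRUE
    }
  }
  out
}
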