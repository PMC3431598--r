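#' Simulate gene-family histories along a species tree
#'
#' Forward simulation of a per-copy linear birth-death process (Gillespie:
#' exponential waiting times between events, each event a duplication or a
#' loss of one copy) along every branch of a time-calibrated species tree.
#' The per-branch true event counts are recorded, which is what makes the
#' output usable as ground truth for reconciliation- and likelihood-based
#' estimators.
#'
#' @param species_tree rooted `phylo` with positive branch lengths (time
#'   units; rates are per copy per unit).
#' @param birth_rate,death_rate non-negative per-copy rates.
#' @param root_size integer copy number at the root.
#' @param n_families number of independent families to simulate.
#' @param seed integer seed.
#' @return A list: `counts` (species x family integer matrix),
#'   `node_sizes` (node x family matrix of copy numbers, tips first),
#'   `events` (`data.table`: family, branch child node, gains, losses),
#'   `extinct` (logical per family: zero copies at every tip).
#' @export
simulate_family_history <- function(species_tree, birth_rate, death_rate,
                                    root_size, n_families, seed = 1L) {
  if (birth_rate < 0 || death_rate < 0) stop("rates must be >= 0", call. = FALSE)
  if (is.null(species_tree$edge.length) ||
      any(species_tree$edge.length <= 0)) {
    stop("species tree needs positive branch lengths", call. = FALSE)
  }
  info <- species_tree_info(species_tree)
  elen <- stats::setNames(species_tree$edge.length, species_tree$edge[, 2])
  ord <- order(info$depth)                     # parents before children
  with_seed(seed, {
    node_sizes <- matrix(0L, nrow = info$n, ncol = n_families)
    gains <- matrix(0L, nrow = info$n, ncol = n_families)
    losses <- matrix(0L, nrow = info$n, ncol = n_families)
    for (f in seq_len(n_families)) {
      node_sizes[info$root, f] <- as.integer(root_size)
      for (v in ord) {
        if (v == info$root) next
        n <- node_sizes[info$parent[v], f]
        t_end <- elen[[as.character(v)]]
        tcur <- 0
        g <- l <- 0L
        rate_sum <- birth_rate + death_rate
        while (n > 0L && rate_sum > 0) {
          dt <- stats::rexp(1L, n * rate_sum)
          tcur <- tcur + dt
          if (tcur > t_end) break
          if (stats::runif(1L) < birth_rate / rate_sum) {
            n <- n + 1L; g <- g + 1L
          } else {
            n <- n - 1L; l <- l + 1L
          }
        }
        node_sizes[v, f] <- n
        gains[v, f] <- g
        losses[v, f] <- l
      }
    }
    counts <- node_sizes[seq_len(info$ntip), , drop = FALSE]
    rownames(counts) <- info$labels
    colnames(counts) <- sprintf("fam%04d", seq_len(n_families))
    ev <- data.table::data.table(
      family = rep(colnames(counts), each = info$n - 1L),
      branch = rep(setdiff(seq_len(info$n), info$root), n_families),
      gains = as.vector(gains[-info$root, , drop = FALSE]),
      losses = as.vector(losses[-info$root, , drop = FALSE]))
    list(counts = counts, node_sizes = node_sizes, events = ev,
         extinct = colSums(counts) == 0L)
  })
}
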