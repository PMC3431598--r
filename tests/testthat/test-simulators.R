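small_spec <- function(seed = 7L) {
  genome_sim_spec(n_scaffolds = 3L, scaffold_length_nt = 200000L,
                  n_intact_genes = 8L, n_pseudogenes = 2L,
                  n_edge_truncated = 2L, tandem_cluster_sizes = c(4L),
                  seed = seed)
}

splice_translate <- function(sim, gid) {
  tg <- sim$truth$genes[sim$truth$genes$id == gid, ]
  ex <- sim$truth$exons[sim$truth$exons$gene_id == gid, ]
  cds <- paste(vapply(seq_len(nrow(ex)), function(k) {
    as.character(chemoreceptR:::genome_subseq(
      sim$genome, tg$scaffold_id, ex$start[k], ex$end[k], tg$strand))
  }, character(1)), collapse = "")
  chemoreceptR:::translate_dna(cds)
}

test_that("genome simulation is bit-identical under a fixed seed", {
  s1 <- simulate_genome(small_spec())
  s2 <- simulate_genome(small_spec())
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$genes, s2$truth$genes)
  expect_identical(s1$queries, s2$queries)
})

test_that("planted intact genes splice into their stated proteins", {
  sim <- simulate_genome(small_spec())
  tg <- sim$truth$genes
  for (g in tg$id[tg$status == "intact"]) {
    aa <- splice_translate(sim, g)
    prot <- tg$protein[tg$id == g]
    expect_identical(substr(aa, 1, nchar(aa) - 1L), prot)
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_gte(nchar(prot), 300L)
  }
})

test_that("planted pseudogenes are disrupted before 300 aa", {
  sim <- simulate_genome(small_spec(seed = 5L))
  tg <- sim$truth$genes
  for (g in tg$id[tg$status == "pseudogene"]) {
    ex <- sim$truth$exons[sim$truth$exons$gene_id == g, ]
    tgr <- tg[tg$id == g, ]
    cum <- 0L
    hit <- FALSE
    for (k in seq_len(nrow(ex))) {
      s <- as.character(chemoreceptR:::genome_subseq(
        sim$genome, tgr$scaffold_id, ex$start[k], ex$end[k], tgr$strand))
      aa <- chemoreceptR:::translate_dna(s)
      stops <- which(strsplit(aa, "")[[1]] == "*")
      if (k == nrow(ex)) stops <- setdiff(stops, nchar(aa))
      if (length(stops) > 0L && cum + stops[1] <= 300L) hit <- TRUE
      cum <- cum + nchar(aa)
    }
    expect_true(hit, info = g)
  }
})

test_that("edge-truncated genes abut a scaffold end or an N-run", {
  sim <- simulate_genome(small_spec(seed = 11L))
  tg <- sim$truth$genes
  lens <- scaffold_lengths(sim$genome)
  for (i in which(tg$status == "partial_assembly")) {
    near_end <- tg$end[i] >= lens[[tg$scaffold_id[i]]] - 5L ||
      tg$start[i] <= 5L
    runs <- n_runs(sim$genome, tg$scaffold_id[i])
    near_n <- nrow(runs) > 0L &&
      any(pmax(runs$start - tg$end[i], tg$start[i] - runs$end, 0L) <= 5L)
    expect_true(near_end || near_n, info = tg$id[i])
    # kept coding is genuinely short of an intact ORF
    expect_lt(nchar(tg$protein[i]), 300L)
  }
})

test_that("planted tandem arrays respect the cluster gap", {
  sim <- simulate_genome(small_spec())
  cl <- sim$truth$clusters
  expect_gte(nrow(cl), 1L)
  for (b in cl$block) {
    members <- sim$truth$genes[sim$truth$genes$block == b &
                                 sim$truth$genes$in_cluster, ]
    members <- members[order(members$start), ]
    expect_equal(length(unique(members$family)), 1L)
    if (nrow(members) > 1L) {
      expect_true(all(diff(members$start) <= 20000L))
    }
  }
})

test_that("over-filled scaffolds are refused", {
  expect_error(
    simulate_genome(genome_sim_spec(n_scaffolds = 1L,
                                    scaffold_length_nt = 50000L,
                                    n_intact_genes = 30L,
                                    n_pseudogenes = 0L,
                                    n_edge_truncated = 0L,
                                    tandem_cluster_sizes = integer())),
    "do not fit")
})

test_that("family histories honour degenerate rates and the seed", {
  tr <- six_taxon_tree()
  h0 <- simulate_family_history(tr, 0, 0, root_size = 25L,
                                n_families = 20L, seed = 1L)
  expect_true(all(h0$counts == 25L))
  expect_equal(sum(h0$events$gains + h0$events$losses), 0L)
  h1 <- simulate_family_history(tr, 0.001, 0.001, 25L, 50L, seed = 9L)
  h2 <- simulate_family_history(tr, 0.001, 0.001, 25L, 50L, seed = 9L)
  expect_identical(h1$counts, h2$counts)
  expect_error(simulate_family_history(tr, -1, 0, 5, 5), ">= 0")
})

test_that("simulated counts are consistent with the per-branch event log", {
  tr <- six_taxon_tree()
  h <- simulate_family_history(tr, 0.002, 0.002, 10L, 100L, seed = 2L)
  info <- chemoreceptR:::species_tree_info(tr)
  for (f in seq_len(ncol(h$counts))) {
    ev <- h$events[h$events$family == colnames(h$counts)[f], ]
    for (j in seq_len(nrow(ev))) {
      v <- ev$branch[j]
      expect_equal(h$node_sizes[v, f],
                   h$node_sizes[info$parent[v], f] + ev$gains[j] - ev$losses[j])
    }
  }
  expect_equal(unname(h$counts[, 1]),
               h$node_sizes[seq_len(info$ntip), 1])
})

test_that("the mean leaf count is a martingale under birth = death", {
  tr <- six_taxon_tree()
  h <- simulate_family_history(tr, 0.001, 0.001, 25L, 500L, seed = 1L)
  m <- colMeans(h$counts)
  se <- stats::sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - 25) / se, 3)
})

test_that("count simulation plants recoverable enrichment", {
  meta <- data.frame(sample = c("w1", "w2", "m1", "m2"), species = "Cf",
                     sex = c("worker", "worker", "male", "male"))
  fc <- stats::setNames(c(4, 0.25), c("gene0001", "gene0002"))
  s1 <- simulate_counts(100, meta, fold_changes = fc, dispersion = 0,
                        seed = 5L)
  s2 <- simulate_counts(100, meta, fold_changes = fc, dispersion = 0,
                        seed = 5L)
  expect_identical(s1$table$counts, s2$table$counts)
  expect_equal(s1$truth$label[1:2], c("worker_enriched", "male_enriched"))
  fpkm <- compute_fpkm(s1$table)
  wk <- rowMeans(fpkm[, meta$sex == "worker"])
  ml <- rowMeans(fpkm[, meta$sex == "male"])
  lab <- classify_enrichment(wk, ml,
                             labels = c("worker_enriched", "male_enriched",
                                        "not_de"))
  expect_identical(unname(lab), s1$truth$label)
})

test_that("null count tables keep the two-fold false-positive rate low", {
  meta <- data.frame(sample = c("w1", "w2", "m1", "m2"), species = "Cf",
                     sex = c("worker", "worker", "male", "male"))
  s <- simulate_counts(1000, meta, seed = 8L)
  fpkm <- compute_fpkm(s$table)
  lab <- classify_enrichment(rowMeans(fpkm[, 1:2]), rowMeans(fpkm[, 3:4]))
  expect_lt(mean(lab != "not_de"), 0.05)
})
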