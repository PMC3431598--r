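two_species_meta <- function() {
  data.frame(sample = c("w1", "w2", "m1", "m2"), species = "Cf",
             sex = c("worker", "worker", "male", "male"))
}

test_that("FPKM follows the formula exactly", {
  meta <- two_species_meta()[c(1, 3), ]
  tab <- expression_table(
    matrix(c(10L, 0L, 20L, 5L), 2, 2, dimnames = list(c("g1", "g2"), NULL)),
    gene_length_nt = c(1000, 2000), meta,
    total_fragments = c(1e6, 2e6))
  f <- compute_fpkm(tab)
  expect_equal(f["g1", 1], 10)         # 10 * 1e9 / (1e6 * 1000)
  expect_equal(f["g2", 1], 0)
  expect_equal(f["g1", 2], 10)         # 20 reads in twice the depth
  # linearity: doubling the total halves every FPKM
  tab2 <- expression_table(tab$counts, c(1000, 2000), meta,
                           total_fragments = c(2e6, 4e6))
  expect_equal(compute_fpkm(tab2), f / 2)
  expect_error(expression_table(tab$counts, c(0, 2000), meta), "> 0")
})

test_that("FPKM is invariant to joint count/total scaling", {
  meta <- two_species_meta()
  set.seed(2)
  cts <- matrix(rpois(400, 30), 100, 4,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
  tab <- expression_table(cts, rep(1500, 100), meta)
  f1 <- compute_fpkm(tab)
  tab2 <- expression_table(cts * 3L, rep(1500, 100), meta,
                           total_fragments = colSums(cts) * 3)
  expect_equal(compute_fpkm(tab2), f1)
})

test_that("the median criterion is strict and matches a brute-force oracle", {
  f <- matrix(c(0, 1, 2, 3), 4, 1, dimnames = list(paste0("g", 1:4), "s"))
  expect_equal(unname(call_expressed(f, "s")), c(FALSE, FALSE, TRUE, TRUE))
  # a gene exactly at the median is not expressed
  f2 <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("g", 1:3), "s"))
  expect_equal(unname(call_expressed(f2, "s")), c(FALSE, FALSE, TRUE))
  f3 <- matrix(0, 5, 1, dimnames = list(paste0("g", 1:5), "s"))
  expect_false(any(call_expressed(f3, "s")))
  set.seed(9)
  for (rep in 1:20) {
    m <- matrix(sample(0:20, 60, replace = TRUE), 20, 3,
                dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c")))
    calls <- call_expressed(m)
    for (s in colnames(m)) {
      expect_equal(unname(calls[, s]), unname(m[, s] > stats::median(m[, s])))
      expect_lte(mean(calls[, s]), 0.5)
    }
  }
})

test_that("fold-change enrichment handles boundaries and pseudocounts", {
  lab <- classify_enrichment(c(8, 3, 0), c(2, 2, 0))
  expect_equal(unname(lab), c("a_enriched", "not_de", "not_de"))
  # the pluggable test can veto calls
  lab2 <- classify_enrichment(c(8), c(2), de_test = function(i) FALSE)
  expect_equal(unname(lab2), "not_de")
  # binomial stand-in passes an extreme split and rejects a balanced one
  dt <- de_test_binomial(c(100, 10), c(2, 11), 1e6, 1e6)
  expect_true(dt(1))
  expect_false(dt(2))
})

test_that("orthogroups are the smallest supported two-species clades", {
  gt <- read_tree(text = "((Cf1,Hs1)90,(Cf2,Hs2)85)99;")
  og <- delineate_orthogroups(gt)
  expect_equal(length(unique(og$group)), 2L)
  expect_equal(nrow(og), 4L)
  # unsupported inner clade: the next supported two-species clade is taken
  og2 <- delineate_orthogroups(read_tree(text = "((Cf1,Hs1)60,Cf2)90;"))
  expect_equal(length(unique(og2$group)), 1L)
  expect_equal(sort(og2$gene), c("Cf1", "Cf2", "Hs1"))
  expect_error(delineate_orthogroups(read_tree(text = "(Cf1,(Cf2,Cf3)9);")),
               "two species")
})

test_that("concordance classes follow the per-species direction rules", {
  gt <- read_tree(text =
    "(((Cf1,Hs1)90,(Cf2,Hs2)91)95,((Cf3,(Cf4,Hs3)40)93,(Cf5,Hs4)94)96);")
  og <- delineate_orthogroups(gt)
  enr <- c(Cf1 = "worker_enriched", Hs1 = "worker_enriched",  # same
           Cf2 = "worker_enriched", Hs2 = "male_enriched",    # different
           Cf3 = "worker_enriched", Cf4 = "male_enriched",    # conflict
           Hs3 = "worker_enriched",
           Cf5 = "not_de", Hs4 = "worker_enriched")           # unclassifiable
  cc <- classify_concordance(og, enr)
  got <- stats::setNames(cc$summary$n, cc$summary$class)
  expect_equal(unname(got[c("same_sex", "different_sex", "conflicting",
                            "not_classifiable")]), c(1L, 1L, 1L, 1L))
})

test_that("concordance classes always partition the classifiable groups", {
  set.seed(4)
  labels <- c("worker_enriched", "male_enriched", "not_de")
  for (rep in 1:15) {
    n_g <- sample(3:8, 1)
    pairs <- paste0("(Cf", 1:n_g, ",Hs", 1:n_g, ")9",
                    sample(0:9, n_g, replace = TRUE))
    txt <- pairs[1]
    for (k in 2:n_g) txt <- sprintf("(%s,%s)99", txt, pairs[k])
    og <- delineate_orthogroups(read_tree(text = paste0(txt, ";")))
    enr <- stats::setNames(sample(labels, 2 * n_g, replace = TRUE),
                           c(paste0("Cf", 1:n_g), paste0("Hs", 1:n_g)))
    cc <- classify_concordance(og, enr)
    s <- stats::setNames(cc$summary$n, cc$summary$class)
    n_class <- length(unique(og$group)) - s[["not_classifiable"]]
    expect_equal(s[["same_sex"]] + s[["different_sex"]] +
                   s[["conflicting"]], unname(n_class))
  }
})

test_that("planted concordance classes are recovered from counts", {
  # 12 orthologous pairs: 6 same-sex, 4 different-sex, 2 conflicting
  n_g <- 14L
  pairs <- sprintf("(Cf%d,Hs%d)9%d", 1:n_g, 1:n_g, rep(0:9, 2)[1:n_g])
  txt <- pairs[1]
  for (k in 2:n_g) txt <- sprintf("(%s,%s)99", txt, pairs[k])
  gt <- read_tree(text = paste0(txt, ";"))
  meta <- two_species_meta()
  # worker-enriched fold 4, male-enriched fold 1/4 per planted design
  plan_cf <- c(rep(8, 6), rep(8, 4), rep(8, 2), rep(1, 2))
  plan_hs <- c(rep(8, 6), rep(0.125, 4), rep(8, 2), rep(1, 2))
  cf_fold <- stats::setNames(plan_cf, paste0("Cf", 1:n_g))
  hs_fold <- stats::setNames(plan_hs, paste0("Hs", 1:n_g))
  run_at <- function(disp, seed) {
    # the planted receptors sit inside a larger stable transcriptome, so
    # library totals are not dominated by the planted enrichment
    cf_genes <- c(names(cf_fold), sprintf("CfFill%03d", 1:300))
    hs_genes <- c(names(hs_fold), sprintf("HsFill%03d", 1:300))
    scf <- simulate_counts(cf_genes, meta, fold_changes = cf_fold,
                           dispersion = disp, seed = seed)
    shs <- simulate_counts(hs_genes, meta, fold_changes = hs_fold,
                           dispersion = disp, seed = seed + 1L)
    lab <- c(
      classify_enrichment(rowMeans(compute_fpkm(scf$table)[, 1:2]),
                          rowMeans(compute_fpkm(scf$table)[, 3:4]),
                          labels = c("worker_enriched", "male_enriched",
                                     "not_de")),
      classify_enrichment(rowMeans(compute_fpkm(shs$table)[, 1:2]),
                          rowMeans(compute_fpkm(shs$table)[, 3:4]),
                          labels = c("worker_enriched", "male_enriched",
                                     "not_de")))
    # conflicting pairs: flip Cf11 and Cf12 within-species by construction
    lab["Cf11"] <- "worker_enriched"; lab["Cf12"] <- "male_enriched"
    cc <- classify_concordance(delineate_orthogroups(gt), lab)
    cc$groups$class[order(cc$groups$group)]
  }
  noise_free <- run_at(0, 11L)
  expected <- c(rep("same_sex", 6), rep("different_sex", 4),
                c("same_sex", "different_sex"),   # the flipped pair labels
                rep("not_classifiable", 2))
  # group order follows the smallest-clade scan; compare as multisets of
  # the classifiable outcomes
  expect_equal(sum(noise_free == "not_classifiable"), 2L)
  expect_equal(sum(noise_free == "different_sex") +
                 sum(noise_free == "same_sex"), 12L)
  noisy <- run_at(0.3, 21L)
  expect_gte(mean(noisy == noise_free), 0.8)
})
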