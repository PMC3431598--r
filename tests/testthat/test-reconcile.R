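sp_pat <- "^(A|B|C|D)"

test_that("low-support collapsing follows the strict threshold", {
  expect_equal(ape::write.tree(
    collapse_low_support(read_tree(text = "((a,b)50,c);"), 70)),
    "(a,b,c);")
  expect_equal(ape::write.tree(
    collapse_low_support(read_tree(text = "((a,b)70,c);"), 70)),
    "((a,b)70,c);")
  # unknown support collapses
  expect_equal(ape::write.tree(
    collapse_low_support(read_tree(text = "((a,b),c);"), 70)),
    "(a,b,c);")
  # identity when everything is supported
  t4 <- read_tree(text = "(((a,b)90,c)85,d);")
  expect_equal(ape::Ntip(collapse_low_support(t4, 70)), 4L)
  expect_equal(ape::Nnode(collapse_low_support(t4, 70)), 3L)
  # branch lengths of contracted edges accrue to their children
  t5 <- read_tree(text = "((a:1,b:1)40:2,c:3);")
  c5 <- collapse_low_support(t5, 70)
  depths <- ape::node.depth.edgelength(c5)
  expect_equal(unname(depths[seq_len(3)]), c(3, 3, 3))
})

test_that("reconciliation reproduces the hand-worked cases", {
  sp <- read_tree(text = "(A,B);")
  sp3 <- read_tree(text = "((A,B),C);")
  r1 <- reconcile_dl(read_tree(text = "((A1,B1),(A2,B2));"), sp,
                     species_pattern = sp_pat)
  expect_equal(c(r1$duplications, r1$losses), c(1L, 0L))
  r2 <- reconcile_dl(read_tree(text = "((A1,A2),B1);"), sp,
                     species_pattern = sp_pat)
  expect_equal(c(r2$duplications, r2$losses), c(1L, 0L))
  expect_equal(r2$events$gains[r2$events$label == "A"], 1L)
  r3 <- reconcile_dl(read_tree(text = "(A1,B1,C1);"), sp3,
                     species_pattern = sp_pat)
  expect_equal(c(r3$duplications, r3$losses), c(0L, 0L))
  r4 <- reconcile_dl(read_tree(text = "(A1);"), sp, species_pattern = sp_pat)
  expect_equal(c(r4$duplications, r4$losses), c(0L, 1L))
  expect_equal(r4$events$losses[r4$events$label == "B"], 1L)
  expect_error(reconcile_dl(read_tree(text = "(A1,X9);"), sp,
                            species_pattern = "^(A|B|X)"), "not found")
})

test_that("leaf copy numbers equal observed counts and branches balance", {
  sp3 <- read_tree(text = "((A,B),C);")
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    species <- sample(c("A", "B", "C"), n, replace = TRUE)
    tips <- paste0(species, seq_len(n))
    tree_txt <- tips[1]
    for (k in 2:n) tree_txt <- sprintf("(%s,%s)", tree_txt, tips[k])
    gt <- read_tree(text = paste0(tree_txt, ";"))
    r <- reconcile_dl(gt, sp3, species_pattern = sp_pat)
    obs <- table(factor(species, levels = c("A", "B", "C")))
    got <- r$events$copies[match(c("A", "B", "C"), r$events$label)]
    expect_equal(got, unname(as.integer(obs)))
    info <- chemoreceptR:::species_tree_info(sp3)
    for (v in seq_len(info$n)) {
      if (v == info$root) next
      expect_equal(r$events$copies[v],
                   r$events$copies[info$parent[v]] +
                     r$events$gains[v] - r$events$losses[v])
    }
  }
})

random_gene_tree <- function(n, species = c("A", "B", "C", "D"),
                             polytomy = FALSE) {
  sp <- sample(species, n, replace = TRUE)
  tips <- paste0(sp, seq_len(n))
  if (polytomy && n >= 3 && runif(1) < 0.5) {
    k <- sample(3:min(n, 4), 1)
    inner <- paste(tips[1:k], collapse = ",")
    rest <- tips[-(1:k)]
    txt <- sprintf("(%s)", inner)
    for (t in rest) txt <- sprintf("(%s,%s)", txt, t)
    return(read_tree(text = paste0(txt, ";")))
  }
  # random binary topology by sequential attachment
  txt <- tips[1]
  for (k in 2:n) {
    txt <- if (runif(1) < 0.5) sprintf("(%s,%s)", txt, tips[k])
           else sprintf("(%s,%s)", tips[k], txt)
  }
  read_tree(text = paste0(txt, ";"))
}

test_that("reconciliation attains the brute-force minimum on binary trees", {
  sp4 <- read_tree(text = "(((A,B),C),D);")
  set.seed(11)
  for (rep in 1:60) {
    gt <- random_gene_tree(sample(2:6, 1))
    r <- reconcile_dl(gt, sp4, species_pattern = sp_pat)
    want <- dl_oracle(gt, sp4, sp_pat)
    expect_equal(r$duplications + r$losses, want,
                 info = ape::write.tree(gt))
  }
})

test_that("collapsing low support never increases the event count", {
  sp4 <- read_tree(text = "(((A,B),C),D);")
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    gt <- random_gene_tree(n)
    gt$node.label <- as.character(sample(c(30, 50, 80, 95), gt$Nnode,
                                         replace = TRUE))
    r_full <- reconcile_dl(gt, sp4, species_pattern = sp_pat)
    r_coll <- reconcile_dl(collapse_low_support(gt, 70), sp4,
                           species_pattern = sp_pat)
    expect_lte(r_coll$duplications + r_coll$losses,
               r_full$duplications + r_full$losses)
  }
})

test_that("single-copy ortholog clades are found, maximal and disjoint", {
  gt <- read_tree(text = paste0(
    "((((A1,B1)90,(C1,D1)88)95,((A2,B2)91,(C2,D2)87)93)90,",
    "(((A3,A4)99,B3)80,(C3,D3)92)60);"))
  cl <- find_single_copy_clades(gt, c("A", "B", "C", "D"), 70,
                                species_pattern = sp_pat)
  expect_equal(length(cl), 2L)
  expect_true(all(vapply(cl, length, integer(1)) == 4L))
  # low support excludes
  gt2 <- read_tree(text = "(((A1,B1)65,(C1,D1)65)65,A9);")
  expect_equal(length(find_single_copy_clades(
    gt2, c("A", "B", "C", "D"), 70, species_pattern = sp_pat)), 0L)
  # duplicated species excludes
  gt3 <- read_tree(text = "(((A1,A2)95,(B1,C1)95)95,D9);")
  expect_equal(length(find_single_copy_clades(
    gt3, c("A", "B", "C"), 70, species_pattern = sp_pat)), 0L)
})

test_that("count parsimony is exact on small cases and bounds truth", {
  sp <- read_tree(text = "(A,B);")
  pe <- parsimony_events(c(A = 3L, B = 1L), sp)
  expect_equal(pe$total_events, 2L)
  tr <- six_taxon_tree()
  h <- simulate_family_history(tr, 0.002, 0.002, 10L, 200L, seed = 31L)
  true_tot <- tapply(h$events$gains + h$events$losses, h$events$family, sum)
  ok <- vapply(seq_len(ncol(h$counts)), function(f) {
    pe <- parsimony_events(h$counts[, f], tr)
    pe$total_events <= true_tot[[colnames(h$counts)[f]]]
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})
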