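test_that("overlapping chains merge into one locus with the best reference", {
  cfg <- pipeline_config()
  h <- as_hsp_table(
    hsp_row(q = "qA", bit = 120, ss = 1000, se = 1299),
    hsp_row(q = "qB", bit = 90, ss = 1200, se = 1499))
  ml <- merge_chains_to_loci(chain_hsps(h, cfg), cfg)
  expect_equal(nrow(ml$loci), 1L)
  expect_equal(ml$loci$ref_query, "qA")
  expect_equal(ml$loci$start, 1000L)
  expect_equal(ml$loci$end, 1499L)
})

test_that("disjoint chains stay separate; ties break lexicographically", {
  cfg <- pipeline_config()
  h <- as_hsp_table(
    hsp_row(q = "qA", bit = 100, ss = 1000, se = 1299),
    hsp_row(q = "qB", bit = 100, ss = 50000, se = 50299))
  ml <- merge_chains_to_loci(chain_hsps(h, cfg), cfg)
  expect_equal(nrow(ml$loci), 2L)
  h2 <- as_hsp_table(
    hsp_row(q = "qB", bit = 100, ss = 1000, se = 1299),
    hsp_row(q = "qA", bit = 100, ss = 1100, se = 1399))
  ml2 <- merge_chains_to_loci(chain_hsps(h2, cfg), cfg)
  expect_equal(ml2$loci$ref_query, "qA")
})

test_that("flanks are clipped to scaffold bounds", {
  cfg <- pipeline_config()
  g <- genome(c(s1 = strrep("A", 3000)))
  h <- as_hsp_table(hsp_row(ss = 100, se = 399))
  ml <- merge_chains_to_loci(chain_hsps(h, cfg), cfg, genome = g)
  expect_equal(ml$loci$flank_start, 1L)
  expect_equal(ml$loci$flank_end, 2399L)
})

test_that("a planted intact gene is recovered from its own HSPs exactly", {
  for (strand in c("+", "-")) {
    pg <- plant_gene(rand_protein(220, seed = 3), n_exons = 2L,
                     strand = strand, seed = 4L)
    idx <- build_search_index(pg$genome)
    h <- search_hsps(idx, c(self = pg$protein))
    cfg <- pipeline_config()
    ml <- merge_chains_to_loci(chain_hsps(filter_hsps(h, cfg), cfg), cfg,
                               pg$genome)
    expect_equal(nrow(ml$loci), 1L)
    m <- predict_gene(ml$loci[1, ], ml$hsps, pg$genome, cfg,
                      family = "OR", query_seq = pg$protein)
    expect_identical(m$translation, pg$protein)
    expect_equal(unname(m$disruptions), c(0L, 0L))
    expect_equal(m$exons, pg$exons, ignore_attr = TRUE)
  }
})

test_that("a planted premature stop is recorded, not fatal", {
  prot <- rand_protein(220, seed = 9)
  pg <- plant_gene(prot, n_exons = 2L, seed = 10L)
  # introduce an in-frame stop at codon 60 of the genome copy
  seqc <- as.character(pg$genome[["chr1"]])
  pos <- pg$exons[1, 1] + 3L * 59L
  substr(seqc, pos, pos + 2L) <- "TAA"
  g2 <- genome(c(chr1 = seqc))
  idx <- build_search_index(g2)
  h <- search_hsps(idx, c(q = prot))
  cfg <- pipeline_config()
  ml <- merge_chains_to_loci(chain_hsps(filter_hsps(h, cfg), cfg), cfg, g2)
  m <- predict_gene(ml$loci[1, ], ml$hsps, g2, cfg, query_seq = prot)
  expect_gte(sum(m$disruptions), 1L)
})

test_that("a locus at the scaffold edge is flagged clipped", {
  prot <- rand_protein(200, seed = 21)
  pg <- plant_gene(prot, n_exons = 2L, seed = 22L)
  # cut the scaffold mid-gene: keep up to the middle of the second exon
  cut_at <- pg$exons[2, 1] + 60L
  g2 <- genome(c(chr1 = substr(as.character(pg$genome[["chr1"]]), 1, cut_at)))
  idx <- build_search_index(g2)
  h <- search_hsps(idx, c(q = prot))
  cfg <- pipeline_config()
  ml <- merge_chains_to_loci(chain_hsps(filter_hsps(h, cfg), cfg), cfg, g2)
  m <- predict_gene(ml$loci[1, ], ml$hsps, g2, cfg, query_seq = prot)
  expect_true(m$clipped)
})

test_that("predict_gene requires supporting HSPs", {
  g <- genome(c(s1 = strrep("ACGT", 100)))
  cfg <- pipeline_config()
  locus <- data.table::data.table(locus_id = 1L, scaffold_id = "s1",
                                  strand = "+", start = 10L, end = 60L,
                                  flank_start = 1L, flank_end = 400L,
                                  ref_query = "nope", n_chains = 0L)
  empty <- chain_hsps(hsp_table(), cfg)
  empty$locus_id <- integer()
  expect_error(predict_gene(locus, empty, g, cfg), "no supporting")
})

test_that("ORF-length quartile filter follows floor and tie rules", {
  mk <- function(len, id) {
    gene_model(id, "OR", "s1", "+", exons = cbind(1L, 3L * len),
               translation = strrep("A", len))
  }
  cfg <- pipeline_config()
  out <- filter_predictions(list(mk(400, "a"), mk(350, "b"), mk(320, "c"),
                                 mk(100, "d")), cfg)
  expect_setequal(vapply(out, `[[`, character(1), "id"), c("a", "b", "c"))
  out2 <- filter_predictions(list(mk(10, "a"), mk(20, "b"), mk(30, "c")), cfg)
  expect_equal(length(out2), 3L)                 # floor(0.75) = 0 removed
  out3 <- filter_predictions(list(mk(50, "a"), mk(50, "b"), mk(50, "c"),
                                  mk(50, "d")), cfg)
  expect_equal(length(out3), 4L)                 # boundary tie retained
  # the filter is per family
  out4 <- filter_predictions(c(
    lapply(1:4, function(i) mk(100 * i, paste0("or", i))),
    list(gene_model("gr1", "GR", "s1", "+", exons = cbind(10000L, 10002L),
                    translation = "A"))), cfg)
  expect_true("gr1" %in% vapply(out4, `[[`, character(1), "id"))
})
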