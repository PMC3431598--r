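# Classification of models into intact / pseudogene / partial_assembly /
# short_unresolved, exercised on constructed micro-genomes.

make_clean_gene <- function(len_aa, pad = 2000L, seed = 1L) {
  prot <- rand_protein(len_aa, seed = seed)
  plant_gene(prot, n_exons = 2L, pad = pad, seed = seed + 100L)
}

model_of <- function(pg, family = "OR", id = "m1") {
  gene_model(id, family, pg$scaffold_id, pg$strand, pg$exons,
             translation = pg$protein)
}

test_that("disruption detection separates clean, broken and terminal stops", {
  pg <- make_clean_gene(320)
  expect_equal(unname(detect_disruptions(model_of(pg), pg$genome)),
               c(0L, 0L))
  # inject one stop into exon 1 (codon 40) and one frameshift-like break
  seqc <- as.character(pg$genome[["chr1"]])
  pos <- pg$exons[1, 1] + 3L * 39L
  substr(seqc, pos, pos + 2L) <- "TAA"
  g2 <- genome(c(chr1 = seqc))
  dis <- detect_disruptions(model_of(pg), g2)
  expect_equal(dis[["premature_stop"]], 1L)
  # exons outside the genome error
  bad <- gene_model("x", "OR", "chr1", "+",
                    exons = cbind(1L, 10 * nchar(seqc)), translation = "M")
  expect_error(detect_disruptions(bad, g2), "outside")
})

test_that("frame-inconsistent near-adjacent segments count as frameshifts", {
  pg <- make_clean_gene(320, seed = 3L)
  # split exon 1 into two pieces with a 1-nt gap (not a codon multiple)
  e1 <- pg$exons[1, ]
  cut <- e1[1] + (((e1[2] - e1[1] + 1L) %/% 2L) %/% 3L) * 3L - 1L
  exons <- rbind(c(e1[1], cut), c(cut + 2L, e1[2] + 1L), pg$exons[2, ] + 1L)
  # rebuild genome with one inserted nt at the cut to keep content
  seqc <- as.character(pg$genome[["chr1"]])
  seqc <- paste0(substr(seqc, 1, cut), "A", substr(seqc, cut + 1, nchar(seqc)))
  m <- gene_model("fs", "OR", "chr1", "+", exons = exons, translation = "M")
  dis <- detect_disruptions(m, genome(c(chr1 = seqc)))
  expect_gte(dis[["frameshift"]], 1L)
})

test_that("classification follows the documented decision order", {
  cfg <- pipeline_config()
  # 320 aa clean OR mid-scaffold -> intact
  pg <- make_clean_gene(320, seed = 5L)
  m <- classify_model(model_of(pg), pg$genome, cfg)
  expect_equal(m$status, "intact")
  # short clean model near a scaffold end -> partial_assembly
  pg2 <- make_clean_gene(150, pad = 2000L, seed = 6L)
  end_cut <- pg2$exons[2, 2] + 800L   # ~1 kb-of-end scaffold
  g2 <- genome(c(chr1 = substr(as.character(pg2$genome[["chr1"]]), 1, end_cut)))
  m2 <- classify_model(model_of(pg2), g2, cfg)
  expect_equal(m2$status, "partial_assembly")
  expect_true(m2$edge_flags[["near_scaffold_end"]])
  # short clean model next to an N-run -> partial_assembly
  pg3 <- make_clean_gene(150, pad = 6000L, seed = 7L)
  seq3 <- as.character(pg3$genome[["chr1"]])
  at <- pg3$exons[2, 2] + 200L
  substr(seq3, at, at + 299L) <- strrep("N", 300L)
  m3 <- classify_model(model_of(pg3), genome(c(chr1 = seq3)), cfg)
  expect_equal(m3$status, "partial_assembly")
  expect_true(m3$edge_flags[["abuts_N_run"]])
  # 299 aa clean mid-scaffold -> short_unresolved (boundary is strict)
  pg4 <- make_clean_gene(299, pad = 6000L, seed = 8L)
  m4 <- classify_model(model_of(pg4), pg4$genome, cfg)
  expect_equal(m4$status, "short_unresolved")
  # any disruption wins over edge proximity
  seq2b <- as.character(g2[["chr1"]])
  pos <- pg2$exons[1, 1] + 3L * 50L
  substr(seq2b, pos, pos + 2L) <- "TGA"
  m5 <- classify_model(model_of(pg2), genome(c(chr1 = seq2b)), cfg)
  expect_equal(m5$status, "pseudogene")
})

test_that("IR intactness requires the domain check to pass", {
  cfg <- pipeline_config()
  pg <- make_clean_gene(320, seed = 9L)
  m_ok <- classify_model(model_of(pg, family = "IR"), pg$genome, cfg)
  expect_equal(m_ok$status, "intact")
  m_no <- classify_model(model_of(pg, family = "IR"), pg$genome, cfg,
                         domain_checker = function(model) FALSE)
  expect_false(m_no$status == "intact")
})

test_that("every model receives exactly one status", {
  cfg <- pipeline_config()
  set.seed(12)
  statuses <- character()
  for (i in 1:6) {
    pg <- make_clean_gene(sample(c(120, 299, 320, 400), 1), seed = 20L + i)
    m <- classify_model(model_of(pg), pg$genome, cfg)
    expect_true(m$status %in% c("intact", "pseudogene", "partial_assembly",
                                "short_unresolved"))
    statuses <- c(statuses, m$status)
  }
  expect_equal(length(statuses), 6L)
})

test_that("the mechanism report mirrors an 80% edge fraction", {
  mk <- function(id, status) {
    gene_model(id, "OR", "s1", "+", exons = cbind(1L, 300L),
               translation = strrep("A", 100), status = status)
  }
  models <- c(lapply(1:8, function(i) mk(paste0("e", i), "partial_assembly")),
              lapply(1:2, function(i) mk(paste0("p", i), "pseudogene")))
  rep <- fragment_mechanism_report(models)
  expect_equal(rep$edge_fraction_of_incomplete[rep$family == "all"], 0.8)
  all_ok <- fragment_mechanism_report(list(mk("a", "intact")))
  expect_equal(all_ok$frac_intact[all_ok$family == "all"], 1)
  expect_equal(nrow(fragment_mechanism_report(list())), 0L)
})
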