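test_that("BLAST tabular HSPs parse with strand normalisation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\ts1\t95.0\t30\t1\t0\t1\t30\t101\t190\t1e-20\t110",
    "q2\ts1\t90.0\t20\t2\t0\t5\t24\t400\t341\t1e-12\t80"), f)
  h <- read_hsp_table(f)
  expect_equal(nrow(h), 2L)
  expect_equal(h$strand, c("+", "-"))
  expect_true(all(h$s_start <= h$s_end))
  expect_equal(h$s_start[2], 341L)
  expect_equal(h$s_end[2], 400L)
})

test_that("malformed HSP rows are rejected by line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t95\t30\t1", ""), f)
  expect_error(read_hsp_table(f), "line 1")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f2)
  expect_equal(nrow(read_hsp_table(f2)), 0L)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t95.0\t30\t1\t0\t1\tXX\t101\t190\t1e-20\t110", f3)
  expect_error(read_hsp_table(f3), "line 1")
})

test_that("HSP tables round-trip through the frames dialect", {
  for (seed in 1:5) {
    h <- random_hsps(20, seed)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_hsp_table(h, f)
    h2 <- read_hsp_table(f, dialect = "blast_tab_frames")
    for (col in c("query_id", "scaffold_id", "q_start", "q_end",
                  "s_start", "s_end", "strand", "frame")) {
      expect_equal(h2[[col]], h[[col]], info = col)
    }
  }
})

test_that("gene models write valid GFF3 and round-trip", {
  m <- gene_model("g1", "OR", "s1", "+",
                  exons = rbind(c(101, 200), c(301, 402)),
                  translation = "MAA", status = "intact")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(list(m), f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  types <- vapply(strsplit(lines[-1], "\t"), `[[`, character(1), 3L)
  expect_equal(types, c("gene", "mRNA", "CDS", "CDS"))
  back <- read_gene_models_gff3(f)
  expect_equal(back[[1]]$exons, m$exons, ignore_attr = TRUE)
  expect_equal(back[[1]]$strand, "+")
  expect_equal(back[[1]]$translation, "MAA")
  expect_equal(back[[1]]$status, "intact")
})

test_that("minus-strand CDS rows are ascending with 3'-to-5' phases", {
  # transcription order: exon of 100 nt then exon of 81 nt
  m <- gene_model("g2", "OR", "s1", "-",
                  exons = rbind(c(201, 300), c(50, 130)),
                  translation = "M")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(list(m), f)
  cds <- strsplit(grep("\tCDS\t", readLines(f), value = TRUE), "\t")
  starts <- as.integer(vapply(cds, `[[`, character(1), 4L))
  phases <- as.integer(vapply(cds, `[[`, character(1), 8L))
  expect_equal(starts, c(50L, 201L))           # ascending file order
  # first CDS in transcription order (201-300, 100 nt) has phase 0; the
  # second needs (3 - 100 %% 3) %% 3 = 2
  expect_equal(phases, c(2L, 0L))
  back <- read_gene_models_gff3(f)
  expect_equal(back[[1]]$exons[, 1], c(201L, 50L), ignore_attr = TRUE)
})

test_that("degenerate GFF3 inputs behave", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(list(), f)
  expect_equal(readLines(f), "##gff-version 3")
  expect_error(
    gene_model("bad", "OR", "s1", "+", exons = rbind(c(1, 100), c(50, 160))),
    "overlap")
})

test_that("newick reading validates and reports supports", {
  tr <- read_tree(text = "((CfOr1,CfOr2)95,HsOr9);")
  expect_equal(node_supports(tr), c(NA_integer_, 95L))
  expect_equal(sort(unique(leaf_species(tr$tip.label))), c("Cf", "Hs"))
  tr2 <- read_tree(text = "((a,b),c);")
  expect_true(all(is.na(node_supports(tr2))))
  expect_error(read_tree(text = "((a,b);"), "parse")
  expect_error(read_tree(text = "((a,a)50,b);"), "duplicate")
})

test_that("genome container enforces its invariants", {
  g <- genome(c(s1 = "acgtn"))
  expect_equal(as.character(g[["s1"]]), "ACGTN")
  expect_error(genome(c(s1 = "ACGR")), "alphabet")
  expect_error(genome(c("ACGT")), "name")
  expect_error(genome(c(s1 = "ACGT", s1 = "ACGT")), "unique")
  g2 <- genome(c(s1 = paste0(strrep("A", 50), strrep("N", 120),
                             strrep("C", 30))))
  runs <- n_runs(g2, "s1")
  expect_equal(runs$start, 51L)
  expect_equal(runs$end, 170L)
})

test_that("genome FASTA round-trips", {
  g <- genome(c(sA = "ACGTACGTAANNTT", sB = "GGGCCCAT"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f)
  g2 <- read_genome_fasta(f)
  expect_equal(as.character(g2), as.character(g))
})
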