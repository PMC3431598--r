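#' Genome container
#'
#' A genome is stored as a named `Biostrings::DNAStringSet` restricted to the
#' A/C/G/T/N alphabet, upper-case, with unique scaffold ids. All coordinates
#' in the package are 1-based inclusive on the forward strand; the strand is
#' always carried separately.
#'
#' @param scaffolds named character vector or `DNAStringSet` of scaffold
#'   sequences.
#' @return A validated `DNAStringSet` (referred to as a "genome"
#'   throughout).
#' @examples
#' g <- genome(c(s1 = "ACGTACGTNN"))
#' scaffold_lengths(g)
#' @export
genome <- function(scaffolds) {
  if (is.character(scaffolds)) {
    scaffolds <- Biostrings::DNAStringSet(toupper(scaffolds))
  }
  if (!methods::is(scaffolds, "DNAStringSet")) {
    stop("'scaffolds' must be a character vector or DNAStringSet", call. = FALSE)
  }
  nm <- names(scaffolds)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop("every scaffold needs a name", call. = FALSE)
  }
  if (anyDuplicated(nm)) stop("scaffold ids must be unique", call. = FALSE)
  if (any(Biostrings::width(scaffolds) == 0L)) {
    stop("scaffold sequences must be non-empty", call. = FALSE)
  }
  freq <- Biostrings::alphabetFrequency(scaffolds)
  bad <- rowSums(freq[, setdiff(colnames(freq), c("A", "C", "G", "T", "N")),
                      drop = FALSE])
  if (any(bad > 0)) {
    stop("scaffold alphabet restricted to A/C/G/T/N", call. = FALSE)
  }
  scaffolds
}

#' @rdname genome
#' @param x a `genome`.
#' @export
scaffold_lengths <- function(x) {
  stats::setNames(Biostrings::width(x), names(x))
}

#' Read / write genome FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that enforce the genome invariants
#' (unique ids, ACGTN alphabet, upper case).
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta` returns a `genome`.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  genome(stats::setNames(toupper(as.character(x)), names(x)))
}

#' @rdname read_genome_fasta
#' @param x a `genome`.
#' @export
write_genome_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Runs of undetermined sequence
#'
#' Locates runs of `N` of at least `min_len` nucleotides in one scaffold;
#' these mark undetermined genomic regions (assembly gaps).
#'
#' @param genome a `genome`.
#' @param scaffold_id scaffold to scan.
#' @param min_len minimum run length (default 100, the length treated as an
#'   assembly gap throughout the package).
#' @return data.frame with columns `start`, `end` (1-based inclusive).
#' @export
n_runs <- function(genome, scaffold_id, min_len = 100L) {
  sc <- genome[[scaffold_id]]
  fr <- Biostrings::alphabetFrequency(sc)
  key <- paste(scaffold_id, length(sc), min_len,
               paste(fr[c("A", "C", "G", "T", "N")], collapse = ":"),
               sep = "|")
  if (!is.null(.n_run_cache[[key]])) return(.n_run_cache[[key]])
  out <- if (fr[["N"]] < min_len) {
    data.frame(start = integer(), end = integer())
  } else {
    m <- gregexpr(sprintf("N{%d,}", as.integer(min_len)),
                  as.character(sc))[[1]]
    if (m[1] == -1L) data.frame(start = integer(), end = integer())
    else data.frame(start = as.integer(m),
                    end = as.integer(m) + attr(m, "match.length") - 1L)
  }
  .n_run_cache[[key]] <- out
  out
}

.n_run_cache <- new.env(parent = emptyenv())

# Internal: extract (possibly minus-strand) subsequence, forward coords.
genome_subseq <- function(genome, scaffold_id, start, end, strand = "+") {
  s <- Biostrings::subseq(genome[[scaffold_id]], start = start, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

# Internal: standard genetic code as a plain lookup table.
.gencode <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

# Internal: translate a DNA string, tolerating N (-> X) and trailing
# partial codons. Plain table lookup: fast for the many small fragments
# the gene predictor translates.
translate_dna <- function(dna) {
  s <- as.character(dna)
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  cods <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- .gencode[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
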