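#' Read a reference genome from FASTA
#'
#' Loads all records of a FASTA file, uppercases the sequences and builds a
#' chromosome index. Record names are truncated at the first whitespace, the
#' usual convention for assembly FASTA headers.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `ref_genome`: a list with elements `sequences`
#'   (a [Biostrings::DNAStringSet]) and `index` (a tibble with columns
#'   `chrom`, `length`). Use [genome_index()] and [get_sequence()] to access.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- read_fasta(fa)
#' genome_index(g)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0) abort_format("empty FASTA file: %s", path)
  if (!startsWith(first, ">")) {
    abort_format("malformed FASTA %s: line 1 does not start with '>'", path)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort_format("malformed FASTA %s: %s", path, conditionMessage(e))
  )
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    abort_format("duplicate FASTA record name: %s",
                 names(seqs)[duplicated(names(seqs))][1])
  }
  empty <- which(Biostrings::width(seqs) == 0)
  if (length(empty) > 0) {
    abort_format("FASTA record %d ('%s') is empty", empty[1], names(seqs)[empty[1]])
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  structure(
    list(
      sequences = seqs,
      index = tibble(chrom = names(seqs), length = Biostrings::width(seqs))
    ),
    class = "ref_genome"
  )
}

#' Construct a reference genome object from in-memory sequences
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @return A `ref_genome` object, as from [read_fasta()].
#' @export
ref_genome <- function(sequences) {
  if (is.character(sequences)) {
    if (is.null(names(sequences))) abort("`sequences` must be named by chromosome")
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  structure(
    list(
      sequences = sequences,
      index = tibble(chrom = names(sequences), length = Biostrings::width(sequences))
    ),
    class = "ref_genome"
  )
}

#' Chromosome index of a genome
#'
#' @param genome A `ref_genome` object.
#' @return A tibble with columns `chrom` and `length` (bp).
#' @export
genome_index <- function(genome) {
  stopifnot(inherits(genome, "ref_genome"))
  genome$index
}

#' Extract (part of) a chromosome sequence
#'
#' @param genome A `ref_genome` object.
#' @param chrom Chromosome name.
#' @param start,end Optional 0-based half-open coordinates; defaults to the
#'   whole chromosome.
#' @return A character scalar (uppercase).
#' @export
get_sequence <- function(genome, chrom, start = NULL, end = NULL) {
  stopifnot(inherits(genome, "ref_genome"))
  if (!chrom %in% names(genome$sequences)) {
    abort(sprintf("unknown chromosome: %s", chrom))
  }
  len <- genome$index$length[genome$index$chrom == chrom]
  start <- start %||% 0L
  end <- end %||% len
  if (start < 0 || end > len || start >= end) {
    abort(sprintf("region [%d,%d) out of bounds for %s (length %d)",
                  start, end, chrom, len))
  }
  as.character(Biostrings::subseq(genome$sequences[[chrom]], start + 1L, end))
}

#' Write a genome to FASTA
#'
#' @param genome A `ref_genome` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "ref_genome"))
  Biostrings::writeXStringSet(genome$sequences, path, width = 70L)
  invisible(path)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %d chromosome(s), %s bp total\n",
              nrow(x$index), format(sum(x$index$length), big.mark = ",")))
  print(x$index)
  invisible(x)
}
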