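#' Read pairwise alignments in AXT format
#'
#' Parses UCSC AXT alignment files (the usual product of a chain/net pipeline)
#' into a tibble of alignment blocks. On disk AXT coordinates are 1-based
#' inclusive; they are converted to 0-based half-open coordinates on read, and
#' both gapped sequences are uppercased. The ungapped reference sequence of
#' every block is checked against the header span.
#'
#' Query-strand `-` blocks are kept as-is: the query sequence in an AXT file
#' is already written in reference orientation, so identity counting does not
#' depend on strand.
#'
#' @param path Path to an AXT file.
#' @param species Identifier of the query species recorded in the output.
#' @return A tibble with one row per alignment block and columns
#'   `species`, `ref_chrom`, `ref_start`, `ref_end` (0-based half-open),
#'   `query_chrom`, `query_start`, `query_end`, `strand`, `score`,
#'   `ref_aligned`, `query_aligned`.
#' @export
read_axt <- function(path, species) {
  if (!file.exists(path)) abort(sprintf("AXT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  body <- lines[nzchar(str_trim(lines))]
  if (length(body) == 0) {
    return(empty_axt_tbl(species))
  }
  if (length(body) %% 3 != 0) {
    abort_format("malformed AXT %s: %d non-blank lines (not a multiple of 3)",
                 path, length(body))
  }
  n_blocks <- length(body) %/% 3
  out <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    hdr <- strsplit(str_trim(body[3 * b - 2]), "\\s+")[[1]]
    if (length(hdr) != 9) {
      abort_format("AXT block %d: header has %d fields, expected 9", b, length(hdr))
    }
    ref_seq <- toupper(body[3 * b - 1])
    qry_seq <- toupper(body[3 * b])
    if (nchar(ref_seq) != nchar(qry_seq)) {
      abort_format("AXT block %d: aligned sequences differ in length (%d vs %d)",
                   b, nchar(ref_seq), nchar(qry_seq))
    }
    ref_start1 <- as.integer(hdr[3]); ref_end1 <- as.integer(hdr[4])
    if (is.na(ref_start1) || is.na(ref_end1)) {
      abort_format("AXT block %d: non-numeric reference coordinates", b)
    }
    ungapped <- nchar(gsub("-", "", ref_seq, fixed = TRUE))
    if (ungapped != ref_end1 - ref_start1 + 1L) {
      abort_format(
        "AXT block %d: header span %d does not match %d ungapped reference bases",
        b, ref_end1 - ref_start1 + 1L, ungapped)
    }
    if (!hdr[8] %in% c("+", "-")) {
      abort_format("AXT block %d: invalid strand '%s'", b, hdr[8])
    }
    out[[b]] <- tibble(
      species = species,
      ref_chrom = hdr[2],
      ref_start = ref_start1 - 1L,
      ref_end = ref_end1,
      query_chrom = hdr[5],
      query_start = as.integer(hdr[6]) - 1L,
      query_end = as.integer(hdr[7]),
      strand = hdr[8],
      score = as.numeric(hdr[9]),
      ref_aligned = ref_seq,
      query_aligned = qry_seq
    )
  }
  bind_rows(out)
}

empty_axt_tbl <- function(species) {
  tibble(
    species = character(), ref_chrom = character(),
    ref_start = integer(), ref_end = integer(),
    query_chrom = character(), query_start = integer(), query_end = integer(),
    strand = character(), score = numeric(),
    ref_aligned = character(), query_aligned = character()
  )
}

#' Write alignment blocks to AXT
#'
#' Inverse of [read_axt()]: internal 0-based half-open coordinates are written
#' back as 1-based inclusive.
#'
#' @param blocks Tibble of alignment blocks as returned by [read_axt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_axt <- function(blocks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (b in seq_len(nrow(blocks))) {
    r <- blocks[b, ]
    writeLines(c(
      paste(b - 1L, r$ref_chrom, r$ref_start + 1L, r$ref_end,
            r$query_chrom, r$query_start + 1L, r$query_end,
            r$strand, format(r$score, scientific = FALSE)),
      r$ref_aligned, r$query_aligned, ""
    ), con)
  }
  invisible(path)
}
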