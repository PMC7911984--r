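# Shared internal helpers: coordinate conversions, sequence utilities and
# format-error signalling. All internal coordinates are 0-based half-open;
# conversion to/from 1-based inclusive happens only at file boundaries.

abort_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "conscore_format_error")
}

# 1-based inclusive (on disk) -> 0-based half-open (internal)
coords_to_internal <- function(start, end) list(start = start - 1L, end = end)

# 0-based half-open (internal) -> 1-based inclusive (on disk)
coords_to_disk <- function(start, end) list(start = start + 1L, end = end)

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Merge possibly-overlapping 0-based half-open intervals into disjoint ones.
merge_intervals <- function(start, end) {
  if (length(start) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Total overlap (bp) of interval [start, end) with a set of intervals.
interval_overlap_bp <- function(start, end, int_start, int_end) {
  if (length(int_start) == 0) return(0L)
  sum(pmax(0L, pmin(end, int_end) - pmax(start, int_start)))
}

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
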