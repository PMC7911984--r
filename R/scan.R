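# Sliding-window identity scan over pairwise alignments. Windows are anchored
# on reference coordinates: a 30-bp window always covers 30 reference bases,
# so detected elements project cleanly onto the reference genome.

#' Scan configuration for conserved-element detection
#'
#' Defaults are the two scans used for mosquito genome conservation work:
#' identity thresholds 90/97/100% over 30-bp windows and 70/90/96/98/100%
#' over 50-bp windows, with a global identity floor of 70%.
#'
#' @param windows Integer vector of window lengths (reference bp).
#' @param thresholds Named list mapping each window length (as a name) to a
#'   numeric vector of identity fractions in (0, 1].
#' @param min_identity Minimal reportable identity; all thresholds must be at
#'   least this.
#' @return An object of class `scan_config`.
#' @export
#' @examples
#' scan_config()
#' scan_config(windows = 30, thresholds = list(`30` = c(0.9, 1)))
scan_config <- function(windows = c(30L, 50L),
                        thresholds = list(`30` = c(0.90, 0.97, 1.00),
                                          `50` = c(0.70, 0.90, 0.96, 0.98, 1.00)),
                        min_identity = 0.70) {
  windows <- as.integer(windows)
  if (any(windows <= 0)) abort("window lengths must be positive")
  if (!setequal(names(thresholds), as.character(windows))) {
    abort("`thresholds` must have one entry per window length")
  }
  th <- unlist(thresholds)
  if (any(th <= 0 | th > 1)) abort("identity thresholds must lie in (0, 1]")
  if (any(th < min_identity)) {
    abort(sprintf("all thresholds must be >= min_identity (%.2f)", min_identity))
  }
  structure(
    list(windows = windows,
         thresholds = thresholds[as.character(windows)],
         min_identity = min_identity),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat("<scan_config>\n")
  for (w in x$windows) {
    cat(sprintf("  window %d bp: thresholds %s\n", w,
                paste(format(x$thresholds[[as.character(w)]]), collapse = ", ")))
  }
  cat(sprintf("  identity floor: %.2f\n", x$min_identity))
  invisible(x)
}

# Per-reference-position match indicator for one gapped alignment block.
# A reference base matches only when the aligned query base is identical and
# both are unambiguous (A/C/G/T): gaps and N count as mismatch. Query
# insertions (gap in the reference row) occupy no reference coordinate.
block_match_vector <- function(ref_aligned, query_aligned) {
  rc <- seq_chars(ref_aligned)
  qc <- seq_chars(query_aligned)
  keep <- rc != "-"
  rc <- rc[keep]
  qc <- qc[keep]
  rc == qc & rc %in% DNA_BASES & qc %in% DNA_BASES
}

#' Per-window identity of an alignment block
#'
#' Slides a window of `window` consecutive reference bases across one
#' alignment block and counts exact matches: with a 50-bp window, 49 matching
#' positions give identity 49/50 = 98%.
#'
#' @param block A one-row tibble (or list) with fields `ref_aligned`,
#'   `query_aligned`, `ref_chrom`, `ref_start` as produced by [read_axt()].
#' @param window Window length in reference bp.
#' @return A tibble with one row per window position: `ref_chrom`, `start`,
#'   `end` (0-based half-open reference coordinates), `matches`, `identity`.
#'   Empty when the block spans fewer than `window` reference bases.
#' @export
window_identity <- function(block, window) {
  m <- block_match_vector(block$ref_aligned[[1]], block$query_aligned[[1]])
  L <- length(m)
  if (window > L) {
    return(tibble(ref_chrom = character(), start = integer(),
                  end = integer(), matches = integer(), identity = numeric()))
  }
  cs <- c(0L, cumsum(m))
  counts <- cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]
  start <- block$ref_start[[1]] + 0:(L - window)
  tibble(
    ref_chrom = block$ref_chrom[[1]],
    start = as.integer(start),
    end = as.integer(start + window),
    matches = as.integer(counts),
    identity = counts / window
  )
}

#' Detect conserved elements by sliding-window identity
#'
#' For every alignment block, window length and identity threshold in the
#' configuration, finds all reference-anchored windows whose identity meets
#' the threshold and merges overlapping qualifying windows (within one
#' (window, threshold) scan) into maximal elements. Each element's identity is
#' the maximum window identity inside it. Windows never span two alignment
#' blocks.
#'
#' @param blocks Tibble of alignment blocks from [read_axt()]; may contain
#'   several species.
#' @param config A [scan_config()].
#' @return Tibble of conserved elements: `species`, `ref_chrom`, `start`,
#'   `end` (0-based half-open), `identity`, `window`, `threshold`.
#' @export
scan_conserved_elements <- function(blocks, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (nrow(blocks) == 0) return(empty_elements_tbl())
  eps <- 1e-9
  out <- list()
  for (b in seq_len(nrow(blocks))) {
    blk <- blocks[b, ]
    for (w in config$windows) {
      wins <- window_identity(blk, w)
      if (nrow(wins) == 0) next
      for (th in config$thresholds[[as.character(w)]]) {
        if (th < config$min_identity) next
        qual <- wins$identity >= th - eps
        if (!any(qual)) next
        merged <- merge_scored_windows(wins$start[qual], w, wins$identity[qual])
        out[[length(out) + 1L]] <- tibble(
          species = blk$species[[1]],
          ref_chrom = blk$ref_chrom[[1]],
          start = merged$start, end = merged$end,
          identity = merged$identity,
          window = as.integer(w), threshold = th
        )
      }
    }
  }
  if (length(out) == 0) return(empty_elements_tbl())
  bind_rows(out) |> arrange(.data$species, .data$ref_chrom, .data$start)
}

empty_elements_tbl <- function() {
  tibble(species = character(), ref_chrom = character(),
         start = integer(), end = integer(), identity = numeric(),
         window = integer(), threshold = numeric())
}

# Merge qualifying windows (all of width w, 0-based starts) into maximal
# runs; per merged element keep the maximum window identity.
merge_scored_windows <- function(starts, w, identities) {
  o <- order(starts)
  starts <- starts[o]; identities <- identities[o]
  ir <- IRanges::IRanges(start = starts + 1L, width = w)
  red <- IRanges::reduce(ir, min.gapwidth = 0L)   # merge overlap, not abutment
  hit <- IRanges::findOverlaps(ir, red)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  tibble(
    start = IRanges::start(red) - 1L,
    end = IRanges::end(red),
    identity = as.numeric(tapply(identities, grp, max))
  )
}

#' Project conserved elements onto a per-base identity matrix
#'
#' Builds the m-species-by-n-bases identity matrix for one chromosome:
#' `I[i, n]` is the maximum identity over all elements of species `i` covering
#' position `n`, and 0 where species `i` has no element (no alignment means
#' no conservation signal).
#'
#' @param elements Element tibble from [scan_conserved_elements()].
#' @param genome A `ref_genome` or [genome_index()] tibble.
#' @param chrom Chromosome to project.
#' @param species Character vector fixing the row order; defaults to the
#'   sorted species present in `elements`.
#' @return A numeric matrix (class `identity_matrix`) with species rownames
#'   and attribute `chrom`; values in `[0, 1]`.
#' @export
project_identity <- function(elements, genome, chrom, species = NULL) {
  idx <- if (inherits(genome, "ref_genome")) genome$index else as_tibble(genome)
  if (!chrom %in% idx$chrom) abort(sprintf("unknown chromosome: %s", chrom))
  n <- idx$length[idx$chrom == chrom]
  species <- species %||% sort(unique(elements$species))
  if (length(species) == 0) abort("no species to project")
  el <- elements[elements$ref_chrom == chrom, ]
  if (!all(el$species %in% species)) {
    abort(sprintf("element species '%s' not in the configured species set",
                  setdiff(unique(el$species), species)[1]))
  }
  bad <- which(el$start < 0 | el$end > n | el$start >= el$end)
  if (length(bad) > 0) {
    abort(sprintf("element %s:%d-%d (%s) out of bounds for length %d",
                  chrom, el$start[bad[1]], el$end[bad[1]], el$species[bad[1]], n))
  }
  I <- matrix(0, nrow = length(species), ncol = n,
              dimnames = list(species, NULL))
  for (k in seq_len(nrow(el))) {
    i <- match(el$species[k], species)
    cols <- (el$start[k] + 1L):el$end[k]
    I[i, cols] <- pmax(I[i, cols], el$identity[k])
  }
  structure(I, chrom = chrom, class = c("identity_matrix", "matrix", "array"))
}
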