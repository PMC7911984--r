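# Per-base score tracks (wiggle/bedGraph), accessibility masks (BED) and the
# ranked target-site table. Tracks are dense numeric vectors, one per
# chromosome, which is the natural unit for per-base conservation scoring.

#' Read a per-base score track from wiggle or bedGraph
#'
#' Expands a fixedStep/variableStep wiggle or bedGraph file (for example a
#' phyloP CONACC score track: positive = conservation, negative =
#' acceleration) into one numeric vector per chromosome. Positions not
#' covered by the file get `fill`, whose default 0 is the neutral score.
#' When records overlap, the record appearing later in the file wins and a
#' warning is emitted.
#'
#' @param path Path to a wiggle (`fixedStep`/`variableStep`) or bedGraph file;
#'   the dialect is detected from the content.
#' @param genome A `ref_genome` (or its [genome_index()] tibble) giving
#'   chromosome names and lengths.
#' @param fill Value for uncovered positions (default 0).
#' @return A named list of numeric vectors, one per chromosome in the index,
#'   each of the chromosome's length.
#' @export
read_score_track <- function(path, genome, fill = 0) {
  if (!file.exists(path)) abort(sprintf("score track not found: %s", path))
  idx <- if (inherits(genome, "ref_genome")) genome$index else as_tibble(genome)
  head_lines <- readLines(path, n = 50L)
  is_wig <- any(grepl("^(fixedStep|variableStep)", head_lines))
  gr <- rtracklayer::import(path, format = if (is_wig) "wig" else "bedGraph")
  rec <- as.data.frame(gr)   # preserves file order; start/end 1-based inclusive
  tracks <- lapply(setNames(idx$length, idx$chrom), function(L) rep(fill, L))
  covered <- lapply(setNames(idx$length, idx$chrom), function(L) raw(L))
  chroms <- as.character(rec$seqnames)
  starts <- rec$start
  ends <- rec$end
  scores <- rec$score
  overlapped <- FALSE
  for (k in seq_along(chroms)) {
    chrom <- chroms[k]
    if (!chrom %in% idx$chrom) {
      abort_format("score track %s: unknown chromosome '%s'", path, chrom)
    }
    L <- idx$length[idx$chrom == chrom]
    if (starts[k] < 1L || ends[k] > L) {
      abort_format("score track %s: position %d-%d outside %s (length %d)",
                   path, starts[k], ends[k], chrom, L)
    }
    span <- starts[k]:ends[k]
    if (any(covered[[chrom]][span] != as.raw(0))) overlapped <- TRUE
    covered[[chrom]][span] <- as.raw(1)
    tracks[[chrom]][span] <- scores[k]
  }
  if (overlapped) {
    warn(sprintf("score track %s has overlapping records; later records win", path))
  }
  tracks
}

#' Write per-base tracks as bedGraph
#'
#' Runs of equal value are merged into single bedGraph records (0-based
#' half-open), so a constant track becomes one line per chromosome. Values
#' are written with full precision: writing a track and re-reading it with
#' [read_score_track()] reproduces the vector exactly.
#'
#' @param tracks Named list of numeric vectors (one per chromosome), or a
#'   single numeric vector together with `chrom`.
#' @param path Output path.
#' @param chrom Chromosome name when `tracks` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path, chrom = NULL) {
  if (is.numeric(tracks)) {
    if (is.null(chrom)) abort("`chrom` is required when `tracks` is a vector")
    tracks <- setNames(list(tracks), chrom)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(tracks)) {
    v <- tracks[[chrom]]
    if (!all(is.finite(v))) abort(sprintf("track %s contains non-finite values", chrom))
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths   # 0-based half-open
    writeLines(sprintf("%s\t%d\t%d\t%.17g", chrom, start, end, r$values), con)
  }
  invisible(path)
}

#' Read an accessibility mask from BED
#'
#' BED intervals (0-based half-open on disk, kept that way internally) are
#' merged at load time so the mask is sorted and non-overlapping.
#'
#' @param path Path to a BED3+ file.
#' @param genome Optional `ref_genome` used to check interval bounds.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   sorted, non-overlapping.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(str_trim(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- str_split(lines, "\t|\\s+")
  n_f <- lengths(fields)
  if (any(n_f < 3)) {
    abort_format("BED %s: line %d has fewer than 3 fields", path, which(n_f < 3)[1])
  }
  tbl <- tibble(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L))
  )
  if (anyNA(tbl$start) || anyNA(tbl$end)) abort_format("BED %s: non-numeric coordinates", path)
  if (any(tbl$end <= tbl$start)) abort_format("BED %s: empty or inverted interval", path)
  if (!is.null(genome)) {
    idx <- genome_index(genome)
    for (i in seq_len(nrow(tbl))) {
      L <- idx$length[idx$chrom == tbl$chrom[i]]
      if (length(L) == 0 || tbl$end[i] > L) {
        abort_format("BED %s: interval %s:%d-%d out of bounds",
                     path, tbl$chrom[i], tbl$start[i], tbl$end[i])
      }
    }
  }
  tbl |>
    group_by(.data$chrom) |>
    group_modify(~ merge_intervals(.x$start, .x$end)) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

#' Write intervals as BED3
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open, written as-is per the BED convention).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  writeLines(sprintf("%s\t%d\t%d", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end)),
             path)
  invisible(path)
}

#' Write conserved elements as BED with identity scores
#'
#' @param elements Tibble from [scan_conserved_elements()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements_bed <- function(elements, path) {
  if (nrow(elements) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t%d", elements$ref_chrom,
    as.integer(elements$start), as.integer(elements$end),
    elements$species, as.integer(round(elements$identity * 1000))
  ), path)
  invisible(path)
}

#' Write the ranked target-site table
#'
#' Coordinates are written 1-based inclusive so a 23-bp site prints as a span
#' such as `2R 48714594 48714616`, the convention used for published gene
#' drive target sites.
#'
#' @param sites Scored (and usually ranked) target-site tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(sites, path) {
  out <- tibble(
    Chromosome = sites$chrom,
    Start = as.integer(sites$start) + 1L,
    End = as.integer(sites$end),
    Strand = sites$strand,
    Cs = sites$cs_mean,
    Cs_max = sites$cs_max,
    Cs_min = sites$cs_min,
    accessible = sites$accessible,
    protospacer = sites$protospacer,
    pam = sites$pam
  )
  readr::write_tsv(out, path)
  invisible(path)
}
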