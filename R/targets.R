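# SpCas9 target-site enumeration and conservation-based ranking. A site is
# the canonical 23-bp unit: a 20-nt protospacer followed by an NGG PAM on the
# site's own strand.

#' Enumerate SpCas9-accessible target sites
#'
#' Scans both strands of a region for 23-bp sites ending in an NGG PAM: on
#' the plus strand every position where bases 22-23 of the site read `GG`,
#' and on the minus strand every position where the site starts with `CC` on
#' the plus strand (i.e. ends in `GG` after reverse complementation). Sites
#' containing `N` and sites truncated by the region boundary are dropped.
#'
#' @param genome A `ref_genome`, or a bare character sequence.
#' @param chrom Chromosome name (when `genome` is a `ref_genome`); used to
#'   label output when a bare sequence is given.
#' @param start,end Optional 0-based half-open region bounds; default is the
#'   whole sequence. Sites must lie entirely inside the region.
#' @return Tibble of unscored sites: `chrom`, `start`, `end` (0-based
#'   half-open, always 23 bp), `strand`, `protospacer` (20-mer on the site's
#'   strand), `pam` (3-mer, NGG on the site's strand).
#' @export
enumerate_cas9_sites <- function(genome, chrom = NULL, start = NULL, end = NULL) {
  if (inherits(genome, "ref_genome")) {
    if (is.null(chrom)) abort("`chrom` is required with a ref_genome")
    len <- genome$index$length[genome$index$chrom == chrom]
    if (length(len) == 0) abort(sprintf("unknown chromosome: %s", chrom))
    seq <- get_sequence(genome, chrom)
  } else {
    seq <- toupper(as.character(genome))
    len <- nchar(seq)
    chrom <- chrom %||% "seq"
  }
  start <- as.integer(start %||% 0L)
  end <- as.integer(end %||% len)
  if (start < 0 || end > len || start > end) {
    abort(sprintf("region [%d,%d) out of bounds (sequence length %d)", start, end, len))
  }
  if (end - start < 23L) return(empty_sites_tbl())
  ch <- seq_chars(seq)
  cand <- start:(end - 23L)                        # 0-based site starts
  has_n <- ch == "N" | !(ch %in% DNA_BASES)
  n_cum <- c(0L, cumsum(has_n))
  clean <- (n_cum[cand + 24L] - n_cum[cand + 1L]) == 0L   # no N in [i, i+23)
  plus <- clean & ch[cand + 22L] == "G" & ch[cand + 23L] == "G"
  minus <- clean & ch[cand + 1L] == "C" & ch[cand + 2L] == "C"
  site_tbl <- function(starts, strand) {
    if (length(starts) == 0) return(empty_sites_tbl())
    site_seq <- substring(seq, starts + 1L, starts + 23L)
    if (strand == "-") site_seq <- revcomp(site_seq)
    tibble(
      chrom = chrom, start = starts, end = starts + 23L, strand = strand,
      protospacer = substr(site_seq, 1L, 20L),
      pam = substr(site_seq, 21L, 23L)
    )
  }
  bind_rows(site_tbl(cand[plus], "+"), site_tbl(cand[minus], "-")) |>
    arrange(.data$start, .data$strand)
}

empty_sites_tbl <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), protospacer = character(), pam = character())
}

#' Attach conservation statistics and accessibility to target sites
#'
#' For each 23-bp site, computes the mean, minimum and maximum of the scaled
#' conservation score over the site, and flags the site inaccessible when it
#' overlaps the accessibility mask by at least one base. Masked sites are
#' kept (flagged, not filtered): high conservation inside masked
#' low-complexity regions should be interpreted cautiously, not discarded
#' silently.
#'
#' @param sites Unscored site tibble from [enumerate_cas9_sites()].
#' @param track A `conservation_track` with `cs_scaled` filled in (see
#'   [minmax_scale()]).
#' @param mask Optional mask tibble (`chrom`, `start`, `end`) from
#'   [read_bed()].
#' @return `sites` with added columns `cs_mean`, `cs_min`, `cs_max`,
#'   `accessible`.
#' @export
score_sites <- function(sites, track, mask = NULL) {
  stopifnot(inherits(track, "conservation_track"))
  if (is.null(track$cs_scaled)) {
    abort("track has no scaled scores; apply minmax_scale() first")
  }
  if (nrow(sites) > 0 && any(sites$end > track$n | sites$start < 0)) {
    bad <- which(sites$end > track$n | sites$start < 0)[1]
    abort(sprintf("site %s:%d-%d extends beyond the conservation track (length %d)",
                  sites$chrom[bad], sites$start[bad], sites$end[bad], track$n))
  }
  cs <- track$cs_scaled
  if (nrow(sites) == 0) {
    out <- bind_cols(sites, tibble(cs_mean = numeric(), cs_min = numeric(),
                                   cs_max = numeric()))
    out$accessible <- logical(0)
    return(out)
  }
  width <- sites$end[1] - sites$start[1]   # all sites share one width (23)
  m <- vapply(seq_len(width), function(o) cs[sites$start + o], numeric(nrow(sites)))
  if (nrow(sites) == 1) m <- matrix(m, nrow = 1)
  out <- bind_cols(sites, tibble(
    cs_mean = as.numeric(rowMeans(m)),
    cs_min = as.numeric(do.call(pmin, asplit(m, 2))),
    cs_max = as.numeric(do.call(pmax, asplit(m, 2)))
  ))
  if (is.null(mask) || nrow(mask) == 0) {
    out$accessible <- rep(TRUE, nrow(out))
  } else {
    out$accessible <- rep(TRUE, nrow(out))
    for (chrom in unique(out$chrom)) {
      mk <- mask[mask$chrom == chrom, ]
      sel <- out$chrom == chrom
      if (nrow(mk) == 0 || !any(sel)) next
      hits <- IRanges::overlapsAny(
        IRanges::IRanges(start = out$start[sel] + 1L, end = out$end[sel]),
        IRanges::IRanges(start = mk$start + 1L, end = mk$end)
      )
      out$accessible[sel] <- !hits
    }
  }
  out
}

#' Rank target sites by conservation
#'
#' Orders sites by mean conservation score (descending), breaking ties by
#' minimum score (descending) and then by coordinates, so the ranking is
#' deterministic and invariant to input order.
#'
#' @param sites Scored site tibble from [score_sites()].
#' @param top_k Keep only the first `top_k` sites (default all).
#' @return The ordered tibble with a leading `rank` column.
#' @export
rank_sites <- function(sites, top_k = Inf) {
  out <- sites |>
    arrange(desc(.data$cs_mean), desc(.data$cs_min),
            .data$chrom, .data$start, .data$strand) |>
    mutate(rank = row_number(), .before = 1)
  if (is.finite(top_k)) out <- head(out, top_k)
  out
}

#' Percentile of a conservation value among positive scores
#'
#' Reports where a score sits within the distribution of all positive scaled
#' conservation values of an arm: the fraction of values less than or equal
#' to it, times 100.
#'
#' @param value Conservation score to place.
#' @param track A `conservation_track` with `cs_scaled`, or a numeric vector
#'   of scores.
#' @return Percentile in `[0, 100]`.
#' @export
percentile_of <- function(value, track) {
  check_scalar_number(value, "value")
  x <- if (inherits(track, "conservation_track")) {
    track$cs_scaled %||% abort("track has no scaled scores; apply minmax_scale() first")
  } else {
    as.numeric(track)
  }
  x <- x[x > 0]
  if (length(x) == 0) abort("no positive conservation values in track")
  mean(x <= value) * 100
}
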