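# The conservation model. Per chromosome arm, the per-base conservation
# score combines three signals:
#
#   cs_raw[n] = mean_i( I[i,n] * d[i] ) * (1 - sigma[n]) / (1 + sigma[n]) * 2^p[n]
#
# where I[i,n] is the windowed alignment identity of species i at base n,
# d[i] the patristic distance of species i to the reference (distant species
# carrying the same identity count for more), sigma[n] the intraspecies SNP
# density in a 20-bp window (variation within the species argues against
# constraint) and p[n] a per-site selection score in the phyloP CONACC
# convention (positive = conservation, negative = acceleration). Raw scores
# are then MinMax-scaled to [0, 1] per chromosome arm.

#' Per-base SNP density track
#'
#' Counts variant positions in a sliding window (default 20 bp) centred on
#' each base and divides by the window span. Windows are truncated at the
#' chromosome ends and the actual span is used as denominator there. For an
#' even window length w the window at base n covers `[n - w/2, n + w/2 - 1]`.
#'
#' @param positions Sorted 0-based variant positions on one chromosome (as
#'   from [read_variant_positions()], one chromosome at a time), or a tibble
#'   with a `pos` column.
#' @param chrom_length Chromosome length in bp.
#' @param window Window length in bp (default 20).
#' @return A numeric vector of length `chrom_length` with values in `[0, 1]`.
#' @export
snp_density <- function(positions, chrom_length, window = 20L) {
  if (is.data.frame(positions)) positions <- positions$pos
  positions <- as.integer(positions)
  if (is.unsorted(positions)) abort("variant positions must be sorted")
  if (length(positions) > 0 &&
      (positions[1] < 0 || positions[length(positions)] >= chrom_length)) {
    abort("variant positions out of chromosome range")
  }
  window <- as.integer(window)
  if (window <= 0) abort("`window` must be positive")
  ind <- integer(chrom_length)
  ind[unique(positions) + 1L] <- 1L        # each variant position counts once
  cs <- cumsum(ind)
  n <- 0:(chrom_length - 1L)
  left <- window %/% 2L
  right <- window - 1L - left
  lo <- pmax(0L, n - left)
  hi <- pmin(chrom_length - 1L, n + right)
  counts <- cs[hi + 1L] - c(0L, cs)[lo + 1L]
  counts / (hi - lo + 1L)
}

#' Weight an identity matrix by phylogenetic distance
#'
#' Multiplies each species row of the per-base identity matrix by that
#' species' distance to the reference, so identical sequence in a
#' phylogenetically distant species contributes more conservation evidence
#' than in a close sibling.
#'
#' @param identity An `identity_matrix` from [project_identity()] (species
#'   rows, base columns).
#' @param distances Tibble with columns `species`, `distance` (as from
#'   [tree_distances()] or [jc69_distance()]), or a named numeric vector.
#' @return The weighted matrix, same shape and class as `identity`.
#' @export
normalize_identity <- function(identity, distances) {
  if (is.data.frame(distances)) {
    d <- setNames(distances$distance, distances$species)
  } else {
    d <- distances
  }
  sp <- rownames(identity)
  if (is.null(sp)) abort("`identity` must have species rownames")
  missing <- setdiff(sp, names(d))
  if (length(missing) > 0) {
    abort(sprintf("no distance for species: %s", paste(missing, collapse = ", ")))
  }
  d <- d[sp]
  if (any(!is.finite(d)) || any(d < 0)) abort("distances must be finite and >= 0")
  out <- identity * d   # rows recycled down columns: element [i,n] * d[i]
  attributes(out) <- attributes(identity)
  out
}

#' Combine identity, SNP density and selection into a raw conservation score
#'
#' For each base n, averages the distance-weighted identities over all m
#' configured species (species without an aligned element contribute 0),
#' down-weights by the intraspecies SNP density factor
#' `(1 - sigma) / (1 + sigma)` and multiplies by the selection factor `2^p`.
#'
#' @param identity_norm Distance-weighted identity matrix from
#'   [normalize_identity()].
#' @param sigma SNP-density vector from [snp_density()] (values in `[0, 1]`);
#'   a scalar 0 is accepted as "no variation data".
#' @param phylop Per-base selection-score vector (phyloP CONACC convention);
#'   a scalar 0 is accepted as "no selection data".
#' @return An object of class `conservation_track`: list with `chrom`,
#'   `n`, `cs_raw`, `cs_scaled` (`NULL` until [minmax_scale()] is applied)
#'   and `scaling`.
#' @export
conservation_score <- function(identity_norm, sigma = 0, phylop = 0) {
  n <- ncol(identity_norm)
  if (length(sigma) == 1) sigma <- rep(sigma, n)
  if (length(phylop) == 1) phylop <- rep(phylop, n)
  if (length(sigma) != n || length(phylop) != n) {
    abort(sprintf("track length mismatch: identity %d, sigma %d, phylop %d",
                  n, length(sigma), length(phylop)))
  }
  if (any(sigma < 0 | sigma > 1)) abort("`sigma` must lie in [0, 1]")
  if (any(!is.finite(phylop))) abort("`phylop` must be finite")
  cs_raw <- colMeans(identity_norm) * (1 - sigma) / (1 + sigma) * 2^phylop
  new_conservation_track(
    chrom = attr(identity_norm, "chrom") %||% NA_character_,
    cs_raw = as.numeric(cs_raw)
  )
}

new_conservation_track <- function(chrom, cs_raw, cs_scaled = NULL,
                                   scaling = "none") {
  structure(
    list(chrom = chrom, n = length(cs_raw), cs_raw = cs_raw,
         cs_scaled = cs_scaled, scaling = scaling),
    class = "conservation_track"
  )
}

#' @export
print.conservation_track <- function(x, ...) {
  cat(sprintf("<conservation_track> %s: %d bp, raw range [%.4g, %.4g], scaling: %s\n",
              x$chrom, x$n, min(x$cs_raw), max(x$cs_raw), x$scaling))
  invisible(x)
}

#' MinMax-scale a conservation track to [0, 1]
#'
#' Applies `(x - min) / (max - min)` so that 1 marks the most conserved base
#' of the scaling domain. The default domain is the single chromosome arm the
#' track belongs to; passing a list of tracks with `domain = "genome"` pools
#' the min and max across all of them (in practice the difference is
#' negligible). A constant domain carries no conservation contrast and maps
#' to all zeros, with a warning.
#'
#' @param x A numeric vector, a `conservation_track`, or a list of
#'   `conservation_track`s.
#' @param domain `"arm"` (per track) or `"genome"` (pooled min/max across a
#'   list of tracks).
#' @param ... Unused.
#' @return Same shape as `x`, with `cs_scaled` filled in for tracks.
#' @export
minmax_scale <- function(x, ...) UseMethod("minmax_scale")

#' @rdname minmax_scale
#' @export
minmax_scale.numeric <- function(x, ...) {
  if (length(x) == 0) abort("cannot MinMax-scale an empty domain")
  if (any(!is.finite(x))) abort("cannot MinMax-scale non-finite values")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warn("constant domain: MinMax scaling maps all values to 0")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' @rdname minmax_scale
#' @export
minmax_scale.conservation_track <- function(x, domain = c("arm", "genome"), ...) {
  domain <- match.arg(domain)
  x$cs_scaled <- minmax_scale(x$cs_raw)
  x$scaling <- "arm"
  x
}

#' @rdname minmax_scale
#' @export
minmax_scale.list <- function(x, domain = c("arm", "genome"), ...) {
  domain <- match.arg(domain)
  stopifnot(all(vapply(x, inherits, logical(1), "conservation_track")))
  if (domain == "arm") {
    return(lapply(x, minmax_scale))
  }
  all_raw <- unlist(lapply(x, `[[`, "cs_raw"))
  if (length(all_raw) == 0) abort("cannot MinMax-scale an empty domain")
  rng <- range(all_raw)
  lapply(x, function(tr) {
    if (rng[1] == rng[2]) {
      warn("constant domain: MinMax scaling maps all values to 0")
      tr$cs_scaled <- rep(0, tr$n)
    } else {
      tr$cs_scaled <- (tr$cs_raw - rng[1]) / (rng[2] - rng[1])
    }
    tr$scaling <- "genome"
    tr
  })
}

#' Windowed average identity for a species group
#'
#' Averages the per-base identity matrix over a subset of species and over
#' consecutive windows (default 1 Mb tiles), reporting percentages - the
#' chromosome-scale conservation profile typically drawn for a close species
#' group versus a distant one. The final window is truncated at the
#' chromosome end and averaged over its actual span.
#'
#' @param identity An `identity_matrix` from [project_identity()].
#' @param species Character vector of species to average (must be rows of
#'   `identity`).
#' @param window Window length in bp (default 1e6).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   `mean_identity` in percent.
#' @export
group_mean_identity <- function(identity, species, window = 1e6) {
  if (length(species) == 0) abort("`species` must be non-empty")
  missing <- setdiff(species, rownames(identity))
  if (length(missing) > 0) {
    abort(sprintf("unknown species in subset: %s", paste(missing, collapse = ", ")))
  }
  window <- as.integer(window)
  n <- ncol(identity)
  col_mean <- colMeans(identity[species, , drop = FALSE])
  starts <- seq(0L, n - 1L, by = window)
  ends <- pmin(starts + window, n)
  tibble(
    chrom = attr(identity, "chrom") %||% NA_character_,
    start = starts,
    end = ends,
    mean_identity = vapply(seq_along(starts), function(k) {
      mean(col_mean[(starts[k] + 1L):ends[k]]) * 100
    }, numeric(1))
  )
}
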