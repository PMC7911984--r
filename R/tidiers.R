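# broom-style accessors for conservation tracks and identity matrices.

#' Tidy a conservation track into a per-base tibble
#'
#' @param x A `conservation_track`.
#' @param ... Unused.
#' @return Tibble with `chrom`, `pos` (0-based), `cs_raw` and (if scaled)
#'   `cs_scaled`.
#' @method tidy conservation_track
#' @export
tidy.conservation_track <- function(x, ...) {
  out <- tibble(chrom = x$chrom, pos = 0:(x$n - 1L), cs_raw = x$cs_raw)
  if (!is.null(x$cs_scaled)) out$cs_scaled <- x$cs_scaled
  out
}

#' One-row summary of a conservation track
#'
#' @param x A `conservation_track`.
#' @param ... Unused.
#' @return A one-row tibble: length, scaling domain, raw mean/max, fraction
#'   of positions with positive score, and scaled mean when available.
#' @method glance conservation_track
#' @export
glance.conservation_track <- function(x, ...) {
  tibble(
    chrom = x$chrom,
    n_bases = x$n,
    scaling = x$scaling,
    cs_raw_mean = mean(x$cs_raw),
    cs_raw_max = max(x$cs_raw),
    prop_positive = mean(x$cs_raw > 0),
    cs_scaled_mean = if (is.null(x$cs_scaled)) NA_real_ else mean(x$cs_scaled)
  )
}

#' Tidy an identity matrix into long per-base form
#'
#' @param x An `identity_matrix`.
#' @param drop_zero Drop rows with identity 0 (default `TRUE`; the matrix is
#'   mostly zeros away from conserved elements).
#' @param ... Unused.
#' @return Long tibble `species`, `pos` (0-based), `identity`.
#' @method tidy identity_matrix
#' @export
tidy.identity_matrix <- function(x, drop_zero = TRUE, ...) {
  out <- tibble(
    species = rep(rownames(x), times = ncol(x)),
    pos = rep(0:(ncol(x) - 1L), each = nrow(x)),
    identity = as.numeric(x)
  )
  if (drop_zero) out <- out[out$identity > 0, ]
  out
}
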