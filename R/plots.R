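# ggplot2 views of the main result types.

#' Plot a conservation track
#'
#' Draws the scaled (or raw) conservation score along the arm, optionally
#' shading masked intervals.
#'
#' @param object A `conservation_track`.
#' @param what `"scaled"` (default, requires [minmax_scale()]) or `"raw"`.
#' @param mask Optional mask tibble (`chrom`, `start`, `end`) drawn as grey
#'   boxes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conservation_track
#' @export
autoplot.conservation_track <- function(object, what = c("scaled", "raw"),
                                        mask = NULL, ...) {
  what <- match.arg(what)
  y <- if (what == "scaled") {
    if (is.null(object$cs_scaled)) abort("track is not scaled; run minmax_scale()")
    object$cs_scaled
  } else {
    object$cs_raw
  }
  df <- tibble(pos = 0:(object$n - 1L), cs = y)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$cs))
  if (!is.null(mask)) {
    mk <- mask[mask$chrom == object$chrom, ]
    if (nrow(mk) > 0) {
      p <- p + ggplot2::annotate(
        "rect", xmin = mk$start, xmax = mk$end, ymin = -Inf, ymax = Inf,
        fill = "grey80", alpha = 0.6)
    }
  }
  p +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(
      x = sprintf("%s position (bp)", object$chrom),
      y = if (what == "scaled") "Cs (scaled)" else "Cs (raw)",
      title = sprintf("Conservation score, %s", object$chrom)) +
    ggplot2::theme_minimal()
}

#' Plot windowed group-identity tracks
#'
#' Chromosome-scale mean identity (percent) for one or more species groups,
#' as produced by [group_mean_identity()] (add a `group` column to overlay
#' several groups).
#'
#' @param data Tibble from [group_mean_identity()], optionally with a
#'   `group` column.
#' @return A ggplot object.
#' @export
plot_group_identity <- function(data) {
  if (!"group" %in% names(data)) data$group <- "all"
  mid <- (data$start + data$end) / 2
  ggplot2::ggplot(
    dplyr::mutate(data, mid = mid),
    ggplot2::aes(x = .data$mid, y = .data$mean_identity, colour = .data$group)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = "mean identity (%)",
                  colour = "species group") +
    ggplot2::theme_minimal()
}

#' Plot ranked Cas9 target sites along a region
#'
#' @param sites Scored/ranked site tibble from [rank_sites()].
#' @param top_k Highlight the `top_k` best-ranked sites (default 5).
#' @return A ggplot object.
#' @export
plot_targets <- function(sites, top_k = 5) {
  sites <- dplyr::mutate(sites, highlight = .data$rank <= top_k)
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$start, y = .data$cs_mean)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$cs_min, ymax = .data$cs_max),
                            colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight,
                                     shape = .data$strand)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "site start (bp)", y = "site mean Cs",
                  shape = "strand") +
    ggplot2::theme_minimal()
}
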