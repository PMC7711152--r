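# ggplot2 front-ends for the result objects.

#' Plot an NMDS ordination
#'
#' @param object an `amendr_nmds` fit.
#' @param metadata optional tibble with `sample_id` plus grouping columns to
#'   join onto the coordinates.
#' @param colour,shape column names (strings) in `metadata` mapped to the
#'   point aesthetics.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.amendr_nmds <- function(object, metadata = NULL, colour = NULL,
                                 shape = NULL, ...) {
  pts <- object$points
  if (!is.null(metadata)) {
    pts <- dplyr::left_join(pts, metadata, by = "sample_id")
  }
  aes_args <- list(x = rlang::sym("NMDS1"), y = rlang::sym("NMDS2"))
  if (!is.null(colour)) aes_args$colour <- rlang::sym(colour)
  if (!is.null(shape)) aes_args$shape <- rlang::sym(shape)
  ggplot2::ggplot(pts, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      subtitle = paste0("stress = ", signif(object$stress, 3))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the permuted ANOSIM R distribution
#'
#' Histogram of the permutation distribution with the observed R marked.
#'
#' @param object an `amendr_anosim` result.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.amendr_anosim <- function(object, ...) {
  df <- tibble(r = object$permuted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "firebrick") +
    ggplot2::labs(
      x = "permuted R", y = "count",
      subtitle = paste0(
        "R = ", signif(object$statistic, 4),
        ", p = ", signif(object$p_value, 3)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot top SIMPER contributions
#'
#' @param object an `amendr_simper` result.
#' @param n number of OTUs per comparison (default 10).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.amendr_simper <- function(object, n = 10, ...) {
  top <- dplyr::slice_head(
    dplyr::group_by(object$contributions, .data$comparison),
    n = n
  )
  ggplot2::ggplot(
    top,
    ggplot2::aes(
      x = .data$average,
      y = stats::reorder(.data$otu_id, .data$average)
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison), scales = "free_y") +
    ggplot2::labs(x = "mean contribution to between-group dissimilarity",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Concentration profile of the diffusing pulse
#'
#' Concentration against distance at one or more elapsed times, with the
#' cartridge window shaded.
#'
#' @param model a [plane_source_model()].
#' @param t_days elapsed times, days.
#' @param x_max largest distance plotted, m.
#' @return a ggplot.
#' @export
plot_concentration_profile <- function(model, t_days = c(37, 74),
                                       x_max = 2.5) {
  grid <- tidyr::expand_grid(
    t_days = t_days,
    x = seq(0.01, x_max, length.out = 400)
  )
  grid <- dplyr::mutate(grid,
    concentration = purrr::map2_dbl(
      .data$x, .data$t_days,
      function(x, td) concentration_at(model, x, days_to_seconds(td))
    ),
    t_label = paste0("t = ", .data$t_days, " d")
  )
  ggplot2::ggplot(grid, ggplot2::aes(.data$x, .data$concentration,
    colour = .data$t_label
  )) +
    ggplot2::annotate("rect",
      xmin = model$near_offset, xmax = model$far_offset,
      ymin = -Inf, ymax = Inf, alpha = 0.12
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "distance from source (m)",
      y = expression(C(x, t) ~ (mol ~ m^-3)), colour = NULL
    ) +
    ggplot2::theme_minimal()
}
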