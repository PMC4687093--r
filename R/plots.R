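#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_area geom_point
#'   geom_histogram geom_abline labs theme_minimal after_stat
NULL

#' @export
ggplot2::autoplot

#' Plot class-pair contact time series
#'
#' @param object A `contact_series` from [contact_time_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_series <- function(object, ...) {
  dat <- mutate(object, pair = paste(.data$class_a, .data$class_b,
                                     sep = "–"))
  ggplot(dat, aes(.data$frame, .data$total, colour = .data$pair)) +
    geom_line() +
    labs(x = "frame", y = "contact number", colour = NULL) +
    theme_minimal()
}

#' Plot binding-state fractions over time
#'
#' @param object A `binding_state_series` from [binding_states()].
#' @param ... Unused.
#' @return A ggplot (stacked per-frame fractions of the eight states).
#' @export
autoplot.binding_state_series <- function(object, ...) {
  frac <- object |>
    group_by(.data$frame, .data$state) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  ggplot(frac, aes(.data$frame, .data$fraction, fill = .data$state)) +
    geom_area(position = "stack") +
    labs(x = "frame", y = "fraction of enzymes", fill = "state") +
    theme_minimal()
}

#' Plot a surface benchmark
#'
#' @param object A `surface_benchmark` from [benchmark_vs_sasa()].
#' @param ... Unused.
#' @return A ggplot of Gaussian vs Shrake-Rupley areas with the identity
#'   line.
#' @export
autoplot.surface_benchmark <- function(object, ...) {
  ggplot(object$pairs, aes(.data$sasa, .data$gaussian)) +
    geom_point() +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "Shrake-Rupley SASA (Å²)",
         y = "Gaussian isosurface area (Å²)") +
    theme_minimal()
}

#' Plot a crossing-angle distribution with the random reference
#'
#' @param angles Numeric angles in degrees (e.g. from [stacking_angles()]).
#' @param bins Histogram bins.
#' @return A ggplot: observed density with the sin(gamma) no-preference
#'   reference curve.
#' @export
plot_stacking_angles <- function(angles, bins = 30) {
  ref <- tibble(angle = seq(0, 90, by = 1),
                density = stacking_reference_density(seq(0, 90, by = 1)))
  ggplot(tibble(angle = angles), aes(.data$angle)) +
    geom_histogram(aes(y = after_stat(density)), bins = bins,
                   fill = "grey70", colour = "grey40") +
    geom_line(data = ref, aes(.data$angle, .data$density), linetype = 2) +
    labs(x = "crossing angle (degrees)", y = "density") +
    theme_minimal()
}

#' Plot an MSD or MSAD curve with its fit window
#'
#' @param object A `diffusion_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diffusion_estimate <- function(object, ...) {
  ycol <- if ("msd" %in% names(object$msd)) "msd" else "msad"
  ggplot(object$msd, aes(.data$lag, .data[[ycol]])) +
    geom_line() +
    geom_point(data = object$msd[object$msd$lag >= object$fit_window[1] &
                                   object$msd$lag <= object$fit_window[2], ],
               colour = "red", size = 0.8) +
    labs(x = "lag (frames)",
         y = if (object$kind == "translational")
           "MSD (Å²)" else "MSAD (rad²)") +
    theme_minimal()
}
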