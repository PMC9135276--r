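# ggplot2 autoplot methods for the fitted/derived result types.

#' @rdname autoplot-spheroidq
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  pts <- object$data |>
    filter(.data$dose_M > 0) |>
    group_by(.data$condition, .data$dose_M) |>
    summarise(viability = mean(.data$viability), .groups = "drop")
  curve <- predict(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$dose_M, y = .data$viability,
                                    colour = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (M)", y = "relative viability",
                  title = "Three-parameter dose-response fit") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-spheroidq
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h, y = .data$confluency)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "time (h)", y = "confluency (%)",
                  title = "Logistic growth fit") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(
      time_h = seq(min(object$data$time_h), max(object$data$time_h), length.out = 200)
    ) |>
      mutate(confluency = object$K / (1 + exp(-object$r * (.data$time_h - object$t0))))
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick") +
      ggplot2::labs(subtitle = sprintf("doubling time %.1f h", object$doubling_time_h))
  }
  p
}

#' @rdname autoplot-spheroidq
#' @method autoplot protection_profile
#' @export
autoplot.protection_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_M, y = .data$c_oe)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$c_oe - .data$c_oe_sem,
                   ymax = .data$c_oe + .data$c_oe_sem),
      width = 0.05, na.rm = TRUE
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$unstable), na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (M)", y = expression(C[O / E]),
                  title = sprintf("Chemoprotection coefficient (%s culture)",
                                  attr(object, "context"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-spheroidq
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_mid, y = .data$mean_intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance to center (px)", y = "mean annulus intensity",
                  title = "Radial intensity profile") +
    ggplot2::theme_minimal()
}

#' Plot methods for spheroidq result objects
#'
#' `autoplot()` methods returning ggplot objects: dose-response fits show
#' points and fitted curves on a log-dose axis; growth fits show the
#' confluency time course and fitted logistic; protection profiles show
#' per-dose `C_O/E` with delta-method error bars; radial profiles and
#' sorting results show intensity against (normalized) distance to center.
#'
#' @param object A fitted/derived spheroidq object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-spheroidq
NULL

#' @rdname autoplot-spheroidq
#' @method autoplot sorting_result
#' @export
autoplot.sorting_result <- function(object, ...) {
  per <- purrr::imap(object$profiles,
                     ~ mutate(as_tibble(.x), spheroid = factor(.y))) |>
    bind_rows()
  ggplot2::ggplot(per, ggplot2::aes(x = .data$r_norm, y = .data$intensity)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$spheroid),
                       alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line(data = object$mean_profile, colour = "firebrick",
                       linewidth = 1, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$statistic$edge_position,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "normalized distance to center",
                  y = "center-normalized intensity",
                  title = "Radial label distribution across spheroids",
                  subtitle = sprintf("edge/center ratio %.2f at %.2f",
                                     object$statistic$edge_center_ratio,
                                     object$statistic$edge_position)) +
    ggplot2::theme_minimal()
}
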