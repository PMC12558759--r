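#' Plot a simulated concentration-time course
#'
#' Intestinal-lumen (and optionally blood) concentration against time on
#' a log10 axis, the conventional presentation for these profiles.
#'
#' @param object a `pk_sim`.
#' @param compartments subset of `c("intestinal", "blood")`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pk_sim <- function(object, compartments = "intestinal", ...) {
  d <- tibble(
    time_h = rep(object$time_h, 2),
    conc = c(object$C_int_ug_per_kg, object$C_b_ug_per_L),
    compartment = rep(c("intestinal", "blood"), each = nrow(object))
  ) %>%
    dplyr::filter(.data$compartment %in% compartments, .data$conc > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$conc,
                                  colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "concentration (µg/L)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay observed profiles on a model prediction
#'
#' @param observations observations table (censored points shown as open
#'   triangles at the LLOQ marker value).
#' @param sim optional `pk_sim` to draw as a line.
#' @return a ggplot object.
#' @export
plot_profiles <- function(observations, sim = NULL) {
  check_profile(observations)
  gg <- ggplot2::ggplot(
    observations,
    ggplot2::aes(.data$time_h, .data$conc_ug_per_kg)
  ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$blq), alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 2),
                                labels = c("observed", "below LLOQ"),
                                name = NULL) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "concentration (µg/kg)") +
    ggplot2::theme_minimal()
  if (!is.null(sim)) {
    gg <- gg + ggplot2::geom_line(
      data = tibble(time_h = sim$time_h,
                    conc_ug_per_kg = sim$C_int_ug_per_kg),
      colour = "steelblue"
    )
  }
  gg
}

#' @rdname pk_sensitivity
#' @param object a `pk_sensitivity`.
#' @export
autoplot.pk_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object$nsc,
                  ggplot2::aes(.data$time_h, .data$nsc,
                               colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-object$cutoff, object$cutoff),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (h)", y = "normalized sensitivity coefficient",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname pk_fit
#' @param object a `pk_fit`.
#' @export
autoplot.pk_fit <- function(object, ...) {
  times <- sort(unique(object$data_fit$time_h))
  grid <- seq(min(times), max(times), length.out = 200)
  sim <- pk_simulate(object$params, object$regimen,
                     times = sort(unique(c(grid, times))),
                     f_mode = object$f_mode, pb_mode = object$pb_mode)
  plot_profiles(
    dplyr::mutate(object$observed,
                  subject_id = if ("subject_id" %in% names(object$observed))
                    .data$subject_id else 1L),
    sim
  )
}
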