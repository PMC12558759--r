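#' Steady-state 24-hour window of a repeating oral regimen
#'
#' Simulates repeated administration until the daily intestinal-lumen
#' Cmax changes by less than `ss_tol` (0.5% by default) between
#' successive days, and returns the concentration series over that final
#' 24-h window (clock time rebased to 0). A single-dose "regimen"
#' (`n_doses = 1`) returns the first 24 h; a zero dose returns a zero
#' window.
#'
#' @param params an [mt_params()] object (its `BW` is used).
#' @param dose_mg_per_kg dose per administration, mg/kg.
#' @param interval_h dosing interval, hours (must divide 24 for the
#'   daily-window comparison).
#' @param n_doses number of doses; `Inf` (default) doses until steady
#'   state.
#' @param ss_tol relative day-over-day Cmax change defining steady state.
#' @param max_days give up (error) after this many days without
#'   convergence.
#' @param dt output resolution of the window, hours.
#' @inheritParams pk_rate_matrix
#' @return tibble of class `pk_window` with `time_h` (0 to 24) and
#'   `C_int_ug_per_kg`; attributes `day` (1-based day returned),
#'   `cmax_ug_per_L`, `dose_mg_per_kg`, `interval_h`.
#' @export
steady_state_window <- function(params, dose_mg_per_kg, interval_h = 8,
                                n_doses = Inf, ss_tol = 0.005,
                                max_days = 30, dt = 0.02,
                                f_mode = c("dose_scale", "systemic_scale"),
                                pb_mode = c("free_fraction", "verbatim")) {
  f_mode <- match.arg(f_mode)
  pb_mode <- match.arg(pb_mode)
  validate_params(params)
  if (interval_h <= 0) stop("interval_h must be positive", call. = FALSE)
  single <- is.finite(n_doses) && n_doses == 1

  if (!single && abs(24 / interval_h - round(24 / interval_h)) > 1e-9) {
    stop("interval_h must divide 24 h for daily steady-state comparison",
         call. = FALSE)
  }
  horizon_days <- if (single) 1 else max_days
  n_total <- if (single) 1 else {
    min(n_doses, ceiling(horizon_days * 24 / interval_h))
  }
  regimen <- regimen_every(dose_mg_per_kg, interval_h, n_total,
                           bw_kg = params$BW)
  times <- seq(0, horizon_days * 24, by = dt)
  sim <- pk_simulate(params, regimen, times = times, f_mode = f_mode,
                     pb_mode = pb_mode)

  window_of <- function(day) {
    w <- dplyr::filter(sim, .data$time_h >= (day - 1) * 24,
                       .data$time_h <= day * 24)
    tibble(time_h = w$time_h - (day - 1) * 24,
           C_int_ug_per_kg = w$C_int_ug_per_kg)
  }

  day <- 1
  if (!single) {
    daily_cmax <- vapply(seq_len(horizon_days),
                         function(d) max(window_of(d)$C_int_ug_per_kg), 0)
    if (all(daily_cmax == 0)) {
      day <- 1
    } else {
      rel <- abs(diff(daily_cmax)) / pmax(daily_cmax[-1], .Machine$double.eps)
      conv <- which(rel < ss_tol)
      if (!length(conv)) {
        stop("no steady state within ", max_days, " days (last daily Cmax ",
             "change ", signif(tail(rel, 1), 3), ")", call. = FALSE)
      }
      day <- conv[1] + 1
    }
  }
  w <- window_of(day)
  structure(w, class = c("pk_window", class(w)),
            day = day, cmax_ug_per_L = max(w$C_int_ug_per_kg),
            dose_mg_per_kg = dose_mg_per_kg, interval_h = interval_h,
            bw_kg = params$BW, f_mode = f_mode)
}

window_conc <- function(window) {
  if (is.data.frame(window)) {
    need <- c("time_h", "C_int_ug_per_kg")
    if (!all(need %in% names(window))) {
      stop("window needs columns time_h and C_int_ug_per_kg", call. = FALSE)
    }
    list(t = window$time_h, c = window$C_int_ug_per_kg)
  } else {
    stop("window must be a data frame", call. = FALSE)
  }
}

#' Percentage of a 24-h window above an effective concentration
#'
#' The PK/PD driver for the regimen recommendation: the percentage of
#' the window during which the intestinal-lumen concentration exceeds
#' the threshold. Crossing times between grid points are located by
#' linear interpolation. Thresholds are in ug/g of intestinal content,
#' equal to ug/mL and to 1000 ug/L under the unit-density convention.
#'
#' @param window a `pk_window` (or any tibble with `time_h`,
#'   `C_int_ug_per_kg` spanning 24 h).
#' @param threshold_ug_per_g effective concentration, ug/g (> 0).
#' @param require_24h check that the window spans 24 h.
#' @return percentage in \[0, 100\].
#' @export
time_above_threshold <- function(window, threshold_ug_per_g,
                                 require_24h = TRUE) {
  if (threshold_ug_per_g <= 0) stop("threshold must be positive",
                                    call. = FALSE)
  w <- window_conc(window)
  span <- max(w$t) - min(w$t)
  if (require_24h && abs(span - 24) > 1e-6) {
    stop("window spans ", span, " h, not 24 h", call. = FALSE)
  }
  thr <- threshold_ug_per_g * 1000  # ug/L
  tt <- w$t
  cc <- w$c
  above <- 0
  for (i in seq_len(length(tt) - 1)) {
    d <- tt[i + 1] - tt[i]
    a1 <- cc[i] > thr
    a2 <- cc[i + 1] > thr
    if (a1 && a2) {
      above <- above + d
    } else if (a1 != a2) {
      frac <- (thr - cc[i]) / (cc[i + 1] - cc[i])
      above <- above + if (a1) d * frac else d * (1 - frac)
    }
  }
  100 * above / span
}

#' Peak-to-threshold ratio
#'
#' Ratio of the window's intestinal Cmax to an effective concentration.
#' `window` may also be a bare numeric Cmax in ug/L.
#'
#' @inheritParams time_above_threshold
#' @param window a `pk_window`, a concentration tibble, or a numeric Cmax
#'   in ug/L.
#' @return dimensionless fold-ratio.
#' @export
cmax_ratio <- function(window, threshold_ug_per_g) {
  if (threshold_ug_per_g <= 0) stop("threshold must be positive",
                                    call. = FALSE)
  cmax <- if (is.numeric(window)) {
    max(window)
  } else {
    max(window_conc(window)$c)
  }
  cmax / (threshold_ug_per_g * 1000)
}

#' Dosage-regimen PK/PD metrics
#'
#' Convenience wrapper: steady-state window, then Cmax ratio and
#' %T>threshold against each effective concentration.
#'
#' @inheritParams steady_state_window
#' @param thresholds_ug_per_g effective-concentration bounds; defaults to
#'   the in vitro resistance-reversal window 300--500 ug/mL.
#' @param ... passed to [steady_state_window()].
#' @return tibble with one row per threshold: regimen descriptors,
#'   steady-state day, `cmax_ug_per_L`, `cmax_ratio`, `pct_above`.
#' @export
regimen_metrics <- function(params, dose_mg_per_kg, interval_h = 8,
                            thresholds_ug_per_g = c(300, 500), ...) {
  w <- steady_state_window(params, dose_mg_per_kg, interval_h, ...)
  purrr::map(thresholds_ug_per_g, function(thr) {
    tibble(
      dose_mg_per_kg = dose_mg_per_kg,
      interval_h = interval_h,
      bw_kg = attr(w, "bw_kg"),
      ss_day = attr(w, "day"),
      threshold_ug_per_g = thr,
      cmax_ug_per_L = attr(w, "cmax_ug_per_L"),
      cmax_ratio = cmax_ratio(w, thr),
      pct_above = time_above_threshold(w, thr)
    )
  }) %>% dplyr::bind_rows()
}
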