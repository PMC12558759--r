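#' Oral dosing regimens
#'
#' A dosing regimen is an ordered table of oral dose events (time in
#' hours, dose in mg/kg) plus the body weight that converts doses per kg
#' into absolute depot amounts: `amount_ug = dose_mg_per_kg x BW x 1000`.
#'
#' @param dose_mg_per_kg dose(s) in mg/kg; recycled against `times_h`.
#' @param times_h administration times in hours, non-decreasing.
#' @param bw_kg body weight in kg.
#' @return a tibble of class `dose_regimen` with columns `time_h`,
#'   `dose_mg_per_kg` and `amount_ug`, and attribute `bw_kg`.
#' @examples
#' dose_regimen(40, 0, bw_kg = 27)                      # single dose
#' dose_regimen(50, seq(0, 96, by = 24), bw_kg = 10)    # 50 mg/kg/d x 5 d
#' @export
dose_regimen <- function(dose_mg_per_kg, times_h = 0, bw_kg = 27) {
  if (length(dose_mg_per_kg) == 1) {
    dose_mg_per_kg <- rep(dose_mg_per_kg, length(times_h))
  }
  if (length(dose_mg_per_kg) != length(times_h)) {
    stop("dose_mg_per_kg and times_h lengths differ", call. = FALSE)
  }
  if (any(dose_mg_per_kg < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(times_h < 0)) stop("dose times must be >= 0", call. = FALSE)
  if (is.unsorted(times_h)) stop("dose times must be non-decreasing",
                                 call. = FALSE)
  if (bw_kg <= 0) stop("bw_kg must be positive", call. = FALSE)
  out <- tibble(
    time_h = as.numeric(times_h),
    dose_mg_per_kg = as.numeric(dose_mg_per_kg),
    amount_ug = as.numeric(dose_mg_per_kg) * bw_kg * 1000
  )
  structure(out, class = c("dose_regimen", class(out)), bw_kg = bw_kg)
}

#' @rdname dose_regimen
#' @param interval_h dosing interval in hours.
#' @param n_doses number of doses.
#' @export
regimen_every <- function(dose_mg_per_kg, interval_h, n_doses,
                          bw_kg = 27) {
  dose_regimen(dose_mg_per_kg,
               times_h = interval_h * (seq_len(n_doses) - 1),
               bw_kg = bw_kg)
}

regimen_bw <- function(regimen) {
  bw <- attr(regimen, "bw_kg")
  if (is.null(bw)) stop("regimen carries no body weight", call. = FALSE)
  bw
}

#' Sampling schedules of the two pig studies
#'
#' `experiment1_schedule()` is the intestinal-content sampling grid of the
#' single-dose cannulated-pig study (0.25--120 h post dose);
#' `experiment2_sacrifice_times()` gives the terminal sampling times of
#' the repeat-dose study (0.5, 1, 3, 6 and 12 days after the last of five
#' daily administrations), expressed in hours since the first dose.
#'
#' @return numeric vector of times in hours.
#' @export
experiment1_schedule <- function() {
  c(0.25, 0.5, 1, 2, 3, 4, 5, 8, 12, 16, 24, 36, 48, 72, 120)
}

#' @rdname experiment1_schedule
#' @export
experiment2_sacrifice_times <- function() {
  96 + c(0.5, 1, 3, 6, 12) * 24
}
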