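#' Observed concentration-time profiles
#'
#' Profiles are plain tibbles with columns `subject_id`, `time_h`,
#' `conc_ug_per_kg` and `blq` (logical below-quantification flag;
#' censored rows carry the LLOQ as a marker value and are excluded from
#' all calculations, except that censored points before the observed peak
#' are treated as zero concentration for AUC purposes).
#'
#' @param subject_id subject identifier (recycled).
#' @param time_h sampling times, strictly increasing within a subject.
#' @param conc_ug_per_kg concentrations in ug/kg (= ug/L under the
#'   unit-density convention).
#' @param blq logical censoring flags.
#' @return a tibble.
#' @export
ct_profile <- function(subject_id, time_h, conc_ug_per_kg,
                       blq = rep(FALSE, length(time_h))) {
  out <- tibble(subject_id = subject_id, time_h = time_h,
                conc_ug_per_kg = conc_ug_per_kg, blq = blq)
  check_profile(out)
  out
}

check_profile <- function(profile) {
  need <- c("time_h", "conc_ug_per_kg", "blq")
  miss <- setdiff(need, names(profile))
  if (length(miss)) {
    stop("profile lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  by_subj <- if ("subject_id" %in% names(profile)) {
    split(profile$time_h, profile$subject_id)
  } else list(profile$time_h)
  if (any(vapply(by_subj, is.unsorted, TRUE, strictly = TRUE))) {
    stop("times must be strictly increasing within subject", call. = FALSE)
  }
  if (any(profile$conc_ug_per_kg < 0, na.rm = TRUE)) {
    stop("negative concentrations", call. = FALSE)
  }
  invisible(profile)
}

# uncensored view used by the NCA components
usable_points <- function(profile) {
  check_profile(profile)
  dplyr::filter(profile, !.data$blq)
}

#' Peak concentration and its time
#'
#' Maximum observed (uncensored) concentration and the time of its first
#' occurrence.
#'
#' @param profile a single-subject profile (see [ct_profile()]).
#' @return one-row tibble with `cmax_ug_per_L` and `tmax_h`.
#' @export
nca_cmax_tmax <- function(profile) {
  u <- usable_points(profile)
  if (!nrow(u)) stop("no uncensored observations", call. = FALSE)
  i <- which.max(u$conc_ug_per_kg)  # which.max takes the first tie
  tibble(cmax_ug_per_L = u$conc_ug_per_kg[i], tmax_h = u$time_h[i])
}

#' Linear trapezoidal area under the curve
#'
#' \eqn{\sum (t_{i+1}-t_i)(C_i + C_{i+1})/2} over observed points with
#' `t_start <= t <= t_end`; no interpolation or extrapolation beyond the
#' observed grid. Censored points at or before the peak count as zero
#' concentration; censored points after the peak are dropped.
#'
#' @param profile a single-subject profile.
#' @param t_end,t_start integration limits in hours.
#' @return AUC in h.ug/L.
#' @export
nca_auc <- function(profile, t_end = max(profile$time_h), t_start = 0) {
  check_profile(profile)
  tmax <- nca_cmax_tmax(profile)$tmax_h
  pts <- profile %>%
    mutate(conc = dplyr::if_else(.data$blq & .data$time_h <= tmax,
                                 0, .data$conc_ug_per_kg)) %>%
    dplyr::filter(!(.data$blq & .data$time_h > tmax)) %>%
    dplyr::filter(.data$time_h >= t_start, .data$time_h <= t_end)
  if (nrow(pts) < 2) {
    stop("fewer than two usable points in [", t_start, ", ", t_end, "]",
         call. = FALSE)
  }
  dt <- diff(pts$time_h)
  sum(dt * (head(pts$conc, -1) + tail(pts$conc, -1)) / 2)
}

#' Terminal log-linear slope
#'
#' Ordinary least squares of `ln(conc)` on time over a terminal point
#' set. The default selection policy scans every suffix of at least
#' `min_points` uncensored, positive-concentration points strictly after
#' the peak and keeps the one with the best adjusted R-squared (ties go
#' to the longer suffix). `lambda_z` is minus the slope.
#'
#' @param profile a single-subject profile.
#' @param min_points minimum number of terminal points (default 3).
#' @return list with `lambda_z` (1/h), `points` (times used), `n`,
#'   `r_squared`, `adj_r_squared`, `intercept` (ln scale).
#' @export
nca_lambda_z <- function(profile, min_points = 3) {
  u <- usable_points(profile)
  tmax <- nca_cmax_tmax(profile)$tmax_h
  term <- dplyr::filter(u, .data$time_h > tmax)
  if (nrow(term) < min_points) {
    stop("need at least ", min_points,
         " uncensored points after the peak (have ", nrow(term), ")",
         call. = FALSE)
  }
  if (any(term$conc_ug_per_kg <= 0)) {
    stop("non-positive terminal concentrations", call. = FALSE)
  }
  starts <- seq_len(nrow(term) - min_points + 1)
  fits <- purrr::map(starts, function(s) {
    tt <- term$time_h[s:nrow(term)]
    yy <- log(term$conc_ug_per_kg[s:nrow(term)])
    n <- length(tt)
    sxx <- sum((tt - mean(tt))^2)
    sxy <- sum((tt - mean(tt)) * (yy - mean(yy)))
    syy <- sum((yy - mean(yy))^2)
    slope <- sxy / sxx
    r2 <- if (syy == 0) 1 else {
      min(1, max(0, sxy^2 / (sxx * syy)))
    }
    list(start = s, n = n, slope = slope,
         intercept = mean(yy) - slope * mean(tt),
         r_squared = r2,
         adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
         points = tt)
  })
  adj <- vapply(fits, `[[`, 0, "adj_r_squared")
  n_pts <- vapply(fits, `[[`, 0, "n")
  best <- fits[[order(-adj, -n_pts)[1]]]
  if (best$slope >= 0) {
    stop("terminal phase has non-negative slope; lambda_z undefined",
         call. = FALSE)
  }
  list(lambda_z = -best$slope, points = best$points, n = best$n,
       r_squared = best$r_squared, adj_r_squared = best$adj_r_squared,
       intercept = best$intercept)
}

#' Terminal half-life
#'
#' `0.693 / lambda_z`, using the conventional rounded constant rather
#' than `log(2)`, to match the reporting convention of the source
#' analyses.
#'
#' @param lambda_z terminal elimination rate constant, 1/h, positive.
#' @return half-life in hours.
#' @export
nca_half_life <- function(lambda_z) {
  if (any(lambda_z <= 0)) stop("lambda_z must be positive", call. = FALSE)
  0.693 / lambda_z
}

#' Full non-compartmental analysis of one profile
#'
#' Assembles the standard oral NCA parameter set: Cmax and Tmax read off
#' the curve, trapezoidal `AUC(0..t_end)`, terminal slope by the
#' adjusted-R-squared suffix policy, `t1/2 = 0.693/lambda_z`,
#' `AUC(0..inf) = AUC(0..tlast) + C_last/lambda_z`, AUMC by trapezoid on
#' `t*C` with the two-term tail `C_last t_last/lambda_z +
#' C_last/lambda_z^2`, `MRT = AUMC_inf/AUC_inf`,
#' `CL/F = dose/AUC_inf` and `V/F = (CL/F)/lambda_z`.
#'
#' @param profile a single-subject profile.
#' @param dose_mg_per_kg administered dose, mg/kg.
#' @param t_end upper limit for the reported partial AUC (h).
#' @param min_points minimum terminal points for the slope.
#' @return one-row tibble with columns `subject_id` (if present),
#'   `cmax_ug_per_L`, `tmax_h`, `auc_0_t`, `auc_0_inf`, `aumc_0_inf`,
#'   `lambda_z`, `t_half_h`, `mrt_h`, `cl_f_L_h_kg`, `v_f_L_kg`,
#'   `lambda_z_n`, `lambda_z_r2`, `lambda_z_adj_r2`, `lambda_z_t_first`.
#' @export
nca <- function(profile, dose_mg_per_kg, t_end = 120, min_points = 3) {
  u <- usable_points(profile)
  ct <- nca_cmax_tmax(profile)
  lz <- nca_lambda_z(profile, min_points)
  t_last <- max(u$time_h)
  c_last <- u$conc_ug_per_kg[u$time_h == t_last]

  auc_t <- nca_auc(profile, t_end = min(t_end, t_last))
  auc_last <- nca_auc(profile, t_end = t_last)
  auc_inf <- auc_last + c_last / lz$lambda_z

  moment <- mutate(u, conc_ug_per_kg = .data$conc_ug_per_kg * .data$time_h)
  aumc_last <- nca_auc(moment, t_end = t_last)
  aumc_inf <- aumc_last + c_last * t_last / lz$lambda_z +
    c_last / lz$lambda_z^2

  cl_f <- dose_mg_per_kg * 1000 / auc_inf  # ug/kg over h.ug/L -> L/h/kg
  out <- tibble(
    cmax_ug_per_L = ct$cmax_ug_per_L,
    tmax_h = ct$tmax_h,
    auc_0_t = auc_t,
    auc_0_inf = auc_inf,
    aumc_0_inf = aumc_inf,
    lambda_z = lz$lambda_z,
    t_half_h = nca_half_life(lz$lambda_z),
    mrt_h = aumc_inf / auc_inf,
    cl_f_L_h_kg = cl_f,
    v_f_L_kg = cl_f / lz$lambda_z,
    lambda_z_n = lz$n,
    lambda_z_r2 = lz$r_squared,
    lambda_z_adj_r2 = lz$adj_r_squared,
    lambda_z_t_first = min(lz$points)
  )
  if ("subject_id" %in% names(profile)) {
    out <- dplyr::bind_cols(
      tibble(subject_id = profile$subject_id[[1]]), out
    )
  }
  out
}

#' Per-subject NCA over a multi-subject table
#'
#' Splits an observations table by `subject_id` and applies [nca()] to
#' each profile, returning one row per subject. Subjects whose profiles
#' do not support a terminal slope (for instance destructive-sampling
#' designs with one point per animal) raise an error unless
#' `strict = FALSE`, in which case they are skipped with a warning.
#'
#' @param observations tibble with `subject_id`, `time_h`,
#'   `conc_ug_per_kg`, `blq`.
#' @inheritParams nca
#' @param strict error (default) or skip on per-subject failure.
#' @return tibble of per-subject NCA rows.
#' @export
nca_by_subject <- function(observations, dose_mg_per_kg, t_end = 120,
                           min_points = 3, strict = TRUE) {
  check_profile(observations)
  split(observations, observations$subject_id) %>%
    purrr::map(function(d) {
      if (strict) return(nca(d, dose_mg_per_kg, t_end, min_points))
      tryCatch(nca(d, dose_mg_per_kg, t_end, min_points),
               error = function(e) {
                 warning("subject ", d$subject_id[[1]], " skipped: ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               })
    }) %>%
    purrr::compact() %>%
    dplyr::bind_rows()
}

#' Group mean profile
#'
#' Arithmetic (default) or geometric mean concentration at each sampling
#' time across subjects, censored points excluded.
#'
#' @param observations multi-subject observations table.
#' @param geometric use the geometric mean.
#' @return tibble `time_h`, `conc_ug_per_kg`, `n`, with `blq = FALSE`.
#' @export
mean_profile <- function(observations, geometric = FALSE) {
  check_profile(observations)
  observations %>%
    dplyr::filter(!.data$blq) %>%
    group_by(.data$time_h) %>%
    summarise(
      conc_ug_per_kg = if (geometric) exp(mean(log(.data$conc_ug_per_kg)))
                       else mean(.data$conc_ug_per_kg),
      n = dplyr::n(), .groups = "drop"
    ) %>%
    mutate(blq = FALSE) %>%
    arrange(.data$time_h)
}
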