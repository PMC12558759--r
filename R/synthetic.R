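#' Virtual cohort specification
#'
#' Describes a synthetic pig study: cohort size, body-weight range,
#' lognormal inter-individual variability (IIV) on selected parameters,
#' multiplicative lognormal residual error, the sampling schedule, the
#' assay quantification limit and the dosing regimen. Defaults emulate
#' the single-dose cannulated-pig study: 6 pigs of 24.3--31.1 kg, one
#' oral dose, intestinal contents sampled 0.25--120 h post dose,
#' censoring at the 2 ug/kg LLOQ. `destructive = TRUE` switches to the
#' repeat-dose sacrifice design (one terminal sample per pig).
#'
#' The IIV magnitudes are generator knobs, not study estimates: the
#' source studies report only observed summary SDs, so the defaults
#' (30% CV on the gastric/absorption/excretion rate constants, none on
#' physiology; 20% residual CV) are conventional round values for oral
#' PK in pigs.
#'
#' @param n_subjects number of virtual pigs.
#' @param bw_range_kg body-weight range, sampled uniformly.
#' @param dose_mg_per_kg dose per administration.
#' @param dose_times_h administration times.
#' @param schedule_h sampling times (h); for destructive designs, the
#'   pool of sacrifice times assigned round-robin.
#' @param iiv_cv named vector of lognormal CVs per parameter.
#' @param residual_cv multiplicative lognormal residual CV.
#' @param lloq_ug_per_kg lower limit of quantification.
#' @param seed integer; expanded to per-subject streams so one subject's
#'   draws do not depend on cohort size.
#' @param destructive one observation time per subject.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 6,
                        bw_range_kg = c(24.3, 31.1),
                        dose_mg_per_kg = 40,
                        dose_times_h = 0,
                        schedule_h = experiment1_schedule(),
                        iiv_cv = c(k_st = 0.3, k_a = 0.3,
                                   k_bi = 0.3, k_e = 0.3),
                        residual_cv = 0.2,
                        lloq_ug_per_kg = 2,
                        seed = 1,
                        destructive = FALSE) {
  stopifnot(n_subjects >= 1, length(bw_range_kg) == 2,
            bw_range_kg[1] <= bw_range_kg[2],
            all(iiv_cv >= 0), residual_cv >= 0, lloq_ug_per_kg > 0)
  if (is.unsorted(schedule_h, strictly = TRUE)) {
    stop("schedule_h must be strictly increasing", call. = FALSE)
  }
  bad <- setdiff(names(iiv_cv), setdiff(param_names(), "BW"))
  if (length(bad)) stop("iiv_cv names not parameters: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(
    n_subjects = n_subjects, bw_range_kg = bw_range_kg,
    dose_mg_per_kg = dose_mg_per_kg, dose_times_h = dose_times_h,
    schedule_h = schedule_h, iiv_cv = iiv_cv,
    residual_cv = residual_cv, lloq_ug_per_kg = lloq_ug_per_kg,
    seed = as.integer(seed), destructive = destructive
  ), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
experiment2_spec <- function(seed = 1, residual_cv = 0.2,
                             iiv_cv = c(k_st = 0.3, k_a = 0.3,
                                        k_bi = 0.3, k_e = 0.3)) {
  cohort_spec(
    n_subjects = 25, bw_range_kg = c(9.8, 10.3),
    dose_mg_per_kg = 50, dose_times_h = seq(0, 96, by = 24),
    schedule_h = experiment2_sacrifice_times(),
    iiv_cv = iiv_cv, residual_cv = residual_cv,
    seed = seed, destructive = TRUE
  )
}

# counter-based per-subject seed streams (kept below 2^31)
subject_seed <- function(seed, subject, purpose = 0L) {
  as.integer((abs(seed) %% 100000L) * 20011L + subject * 7L +
               purpose * 3L) %% 2147483647L
}

# lognormal with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Draw a virtual cohort
#'
#' Per-subject parameter sets: each varied parameter is the base value
#' times a mean-one lognormal deviate with the specified CV; body weight
#' is uniform over the range. Each subject consumes its own seeded
#' stream, so cohorts are reproducible and subject `i` is identical in
#' any cohort with the same seed.
#'
#' @param spec a [cohort_spec()].
#' @param base baseline `mt_params` (the generating "truth").
#' @return tibble with `subject_id`, `bw_kg` and one column per model
#'   parameter; attribute `spec` carries the specification.
#' @export
sample_cohort <- function(spec, base = mt_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_params(base)
  rows <- purrr::map(seq_len(spec$n_subjects), function(i) {
    set.seed(subject_seed(spec$seed, i, 0L))
    bw <- runif(1, spec$bw_range_kg[1], spec$bw_range_kg[2])
    p <- unclass(base)
    p$BW <- bw
    for (nm in names(spec$iiv_cv)) {
      p[[nm]] <- p[[nm]] * rlnorm_cv(1, spec$iiv_cv[[nm]])
    }
    dplyr::bind_cols(tibble(subject_id = i, bw_kg = bw),
                     as_tibble(p[param_names()]))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "spec") <- spec
  out
}

#' Generate observed-like concentration data from a cohort
#'
#' Simulates every subject under the regimen, applies multiplicative
#' lognormal residual error, censors below the LLOQ (the stored value is
#' the LLOQ marker and `blq = TRUE`; the underlying value is withheld)
#' and returns a tidy observations table. In destructive mode each
#' subject contributes one sacrifice time, assigned round-robin over the
#' schedule.
#'
#' @param cohort tibble from [sample_cohort()].
#' @param spec the matching [cohort_spec()]; defaults to the one attached
#'   to `cohort`.
#' @inheritParams pk_rate_matrix
#' @return tibble `subject_id`, `time_h`, `conc_ug_per_kg`, `blq`;
#'   attribute `true_conc` holds the noise-free model concentrations.
#' @export
generate_observations <- function(cohort, spec = attr(cohort, "spec"),
                                  f_mode = c("dose_scale",
                                             "systemic_scale"),
                                  pb_mode = c("free_fraction",
                                              "verbatim")) {
  stopifnot(inherits(spec, "cohort_spec"))
  f_mode <- match.arg(f_mode)
  pb_mode <- match.arg(pb_mode)
  horizon <- max(spec$schedule_h)
  if (any(spec$dose_times_h > horizon)) {
    stop("dose times fall outside the sampling horizon", call. = FALSE)
  }
  n_sched <- length(spec$schedule_h)
  obs <- purrr::map(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    p <- params_from_row(row)
    regimen <- dose_regimen(spec$dose_mg_per_kg, spec$dose_times_h,
                            bw_kg = p$BW)
    times <- if (spec$destructive) {
      spec$schedule_h[((i - 1) %% n_sched) + 1]
    } else {
      spec$schedule_h
    }
    sim <- pk_simulate(p, regimen, times = sort(unique(c(times))),
                       f_mode = f_mode, pb_mode = pb_mode)
    truth <- sim$C_int_ug_per_kg[match(times, sim$time_h)]
    set.seed(subject_seed(spec$seed, row$subject_id[[1]], 1L))
    noisy <- truth * rlnorm_cv(length(truth), spec$residual_cv)
    blq <- noisy < spec$lloq_ug_per_kg
    tibble(
      subject_id = row$subject_id[[1]],
      time_h = times,
      conc_ug_per_kg = ifelse(blq, spec$lloq_ug_per_kg, noisy),
      blq = blq,
      true_conc = truth
    )
  }) %>% dplyr::bind_rows()
  truth <- select(obs, "subject_id", "time_h", "true_conc")
  out <- select(obs, -"true_conc")
  attr(out, "true_conc") <- truth
  out
}
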