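#' Negative log-likelihood of observed intestinal concentrations
#'
#' Simulates the model at the observation times and scores the uncensored
#' points under the chosen residual-error model. The default is
#' log-normal (additive Gaussian on the log concentration) -- the
#' profiles span several orders of magnitude -- with the residual
#' standard deviation profiled out analytically, so the returned value is
#' the NLL at the conditional maximum-likelihood sigma. Censored
#' (below-LLOQ) points are excluded.
#'
#' @param params candidate `mt_params`.
#' @param observed observations table (`time_h`, `conc_ug_per_kg`, `blq`;
#'   `subject_id` optional). All uncensored rows are scored.
#' @param regimen a [dose_regimen()].
#' @param error_model `"lognormal"` (default) or `"normal"` (additive on
#'   the concentration scale).
#' @inheritParams pk_rate_matrix
#' @param validate check parameter invariants before simulating.
#' @return a finite scalar; non-positive predictions at uncensored points
#'   under the log-normal model return a large finite penalty rather than
#'   `NaN` so that simplex search can recover.
#' @export
pk_nll <- function(params, observed, regimen,
                   error_model = c("lognormal", "normal"),
                   f_mode = c("dose_scale", "systemic_scale"),
                   pb_mode = c("free_fraction", "verbatim"),
                   validate = TRUE) {
  error_model <- match.arg(error_model)
  check_profile(observed)
  obs <- dplyr::filter(observed, !.data$blq)
  if (!nrow(obs)) stop("no uncensored observations", call. = FALSE)

  times <- sort(unique(obs$time_h))
  sim <- tryCatch(
    pk_simulate(params, regimen, times = times, f_mode = f_mode,
                pb_mode = pb_mode, validate = validate),
    error = function(e) NULL
  )
  if (is.null(sim)) return(1e9)
  pred <- sim$C_int_ug_per_kg[match(obs$time_h, sim$time_h)]
  n <- length(pred)

  if (error_model == "lognormal") {
    if (any(obs$conc_ug_per_kg <= 0)) {
      stop("log-normal error model requires positive observations",
           call. = FALSE)
    }
    if (any(pred <= 0)) {
      return(1e8 + sum(pmax(0, -pred)) + sum(pred <= 0))
    }
    r <- log(obs$conc_ug_per_kg) - log(pred)
    s2 <- max(mean(r^2), 1e-12)  # floor keeps the zero-residual optimum finite
    n / 2 * (log(2 * pi * s2) + 1) + sum(log(obs$conc_ug_per_kg))
  } else {
    r <- obs$conc_ug_per_kg - pred
    s2 <- max(mean(r^2), 1e-12)
    n / 2 * (log(2 * pi * s2) + 1)
  }
}

default_bounds <- function(name) {
  switch(name,
    k_st = , k_a = c(1e-4, 20),
    k_e = , k_bi = c(1e-5, 20),
    F = , Pb = , PCV = c(1e-6, 1 - 1e-6),
    Qc_l = , Qc_ot = c(1e-6, 1 - 1e-6),
    Vc_int = , Vc_l = , Vc_b = , Vc_ot = c(1e-6, 1 - 1e-6),
    P_l = , P_ot = c(0.01, 100),
    Cl_renal = c(1e-4, 50),
    Qcar = c(0.1, 50),
    stop("no default bounds for ", name, call. = FALSE)
  )
}

to_unconstrained <- function(x, lo, hi) stats::qlogis((x - lo) / (hi - lo))
from_unconstrained <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)

#' Fit model parameters by Nelder-Mead maximum likelihood
#'
#' Derivative-free simplex minimization of [pk_nll()] over a chosen
#' parameter subset, each parameter mapped to the real line by a logistic
#' transform of its biological-plausibility bounds so the search can
#' never leave them. By default the multi-subject data are collapsed to
#' the geometric-mean profile (the fitted data set is one group's mean
#' curve); `pool = "pooled"` scores every subject point instead. A small
#' number of seeded random restarts in the transformed space guards
#' against simplex collapse.
#'
#' @param observed observations table.
#' @param regimen a [dose_regimen()].
#' @param start starting `mt_params` (e.g. [mt_params_start()]).
#' @param fit character vector of parameter names to optimize.
#' @param lower,upper optional named bounds overriding the defaults.
#' @param pool `"geomean"` or `"pooled"`.
#' @param rebalance recompute the closure fractions `Qc_ot`, `Vc_ot` after
#'   each proposal (see [update_params()]).
#' @param restarts maximum random restarts after the initial run.
#' @param seed integer seed for the restart jitter.
#' @param maxit,reltol passed to [stats::optim()] (Nelder-Mead).
#' @inheritParams pk_nll
#' @return an object of class `pk_fit`: access the fitted parameter set
#'   with `$params`, per-parameter estimates with [tidy()], fit summary
#'   with [glance()], and an observed-vs-fitted overlay with
#'   [autoplot()].
#' @export
pk_fit <- function(observed, regimen, start = mt_params_start(),
                   fit = c("k_st", "k_a", "k_bi", "k_e"),
                   lower = NULL, upper = NULL,
                   error_model = c("lognormal", "normal"),
                   pool = c("geomean", "pooled"),
                   f_mode = c("dose_scale", "systemic_scale"),
                   pb_mode = c("free_fraction", "verbatim"),
                   rebalance = TRUE, restarts = 3, seed = 1,
                   maxit = 2000, reltol = 1e-8) {
  error_model <- match.arg(error_model)
  pool <- match.arg(pool)
  f_mode <- match.arg(f_mode)
  pb_mode <- match.arg(pb_mode)
  validate_params(start)
  bad <- setdiff(fit, setdiff(param_names(), "BW"))
  if (length(bad)) stop("cannot fit: ", paste(bad, collapse = ", "),
                        call. = FALSE)

  data_fit <- if (pool == "geomean") mean_profile(observed, geometric = TRUE)
              else observed

  lo <- vapply(fit, function(nm) {
    if (!is.null(lower) && nm %in% names(lower)) lower[[nm]]
    else default_bounds(nm)[1]
  }, 0)
  hi <- vapply(fit, function(nm) {
    if (!is.null(upper) && nm %in% names(upper)) upper[[nm]]
    else default_bounds(nm)[2]
  }, 0)
  if (any(!(lo < hi))) stop("bounds must satisfy lower < upper",
                            call. = FALSE)
  x0 <- pmin(pmax(unlist(start[fit]), lo * 1.0000001), hi * 0.9999999)
  z0 <- to_unconstrained(x0, lo, hi)

  objective <- function(z) {
    x <- from_unconstrained(z, lo, hi)
    cand <- tryCatch(
      update_params(start, setNames(as.list(x), fit),
                    rebalance = rebalance),
      error = function(e) NULL
    )
    if (is.null(cand)) return(1e9)
    pk_nll(cand, data_fit, regimen, error_model = error_model,
           f_mode = f_mode, pb_mode = pb_mode, validate = FALSE)
  }

  run_nm <- function(z) {
    # suppressWarnings: optim() warns that 1-D Nelder-Mead is unreliable,
    # but single-parameter batches are a supported use; restarts cover it
    suppressWarnings(
      optim(z, objective, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol))
    )
  }

  best <- run_nm(z0)
  evals <- best$counts[["function"]]
  used <- 0
  if (restarts > 0) {
    set.seed(seed)
    for (i in seq_len(restarts)) {
      cand <- run_nm(best$par + rnorm(length(z0), sd = 0.5))
      evals <- evals + cand$counts[["function"]]
      if (cand$value < best$value - 1e-8) {
        best <- cand
        used <- used + 1
      }
    }
  }

  est <- from_unconstrained(best$par, lo, hi)
  final <- update_params(start, setNames(as.list(est), fit),
                         rebalance = rebalance)
  structure(list(
    params = final,
    estimates = tibble(term = fit, start = unname(unlist(start[fit])),
                       estimate = unname(est), lower = unname(lo),
                       upper = unname(hi)),
    nll = best$value,
    convergence = best$convergence,
    fn_evals = evals,
    restarts_used = used,
    error_model = error_model, pool = pool,
    f_mode = f_mode, pb_mode = pb_mode,
    observed = observed, data_fit = data_fit, regimen = regimen
  ), class = "pk_fit")
}

#' Batched parameter optimization
#'
#' Optimizes groups of parameters sequentially (each batch fitted with
#' all other parameters held at their current values), mirroring the
#' staged optimization used for the published model. The result of each
#' batch seeds the next.
#'
#' @param batches list of character vectors of parameter names.
#' @inheritParams pk_fit
#' @param ... passed to [pk_fit()].
#' @return the `pk_fit` of the final batch, whose `$batch_history` lists
#'   each batch's fitted values.
#' @export
pk_fit_batches <- function(observed, regimen, start = mt_params_start(),
                           batches = list(c("k_st", "k_a"),
                                          c("k_bi", "k_e")),
                           ...) {
  current <- start
  history <- list()
  fit_obj <- NULL
  for (b in seq_along(batches)) {
    fit_obj <- pk_fit(observed, regimen, start = current,
                      fit = batches[[b]], ...)
    current <- fit_obj$params
    history[[b]] <- fit_obj$estimates
  }
  fit_obj$batch_history <- history
  fit_obj
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> Nelder-Mead maximum-likelihood fit (",
      x$error_model, " error, ", x$pool, " data)\n", sep = "")
  print(as.data.frame(x$estimates), row.names = FALSE)
  cat("NLL:", format(x$nll), " evaluations:", x$fn_evals,
      " convergence code:", x$convergence, "\n")
  invisible(x)
}

#' @rdname pk_fit
#' @param x a `pk_fit` object.
#' @param ... unused.
#' @export
tidy.pk_fit <- function(x, ...) x$estimates

#' @rdname pk_fit
#' @export
glance.pk_fit <- function(x, ...) {
  tibble(nll = x$nll, n_obs = sum(!x$data_fit$blq),
         fn_evals = x$fn_evals, convergence = x$convergence,
         restarts_used = x$restarts_used, error_model = x$error_model,
         pool = x$pool)
}
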