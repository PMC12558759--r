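#' Predicted-versus-observed regression and correlation
#'
#' Ordinary least squares of observed on predicted concentrations plus a
#' Pearson correlation test, the standard goodness-of-prediction summary
#' for a PBPK model evaluated against an external data set.
#'
#' @param data a data frame of paired values.
#' @param predicted,observed columns holding the pairs (bare names or
#'   strings; default column names `predicted` and `observed`).
#' @return one-row tibble: `n`, `slope`, `intercept`, `r`, `r_p_value`.
#' @examples
#' d <- tibble::tibble(pred = c(1, 2, 3), obs = c(2, 4, 6))
#' eval_pred_obs(d, pred, obs)
#' @export
eval_pred_obs <- function(data, predicted = "predicted",
                          observed = "observed") {
  x <- dplyr::pull(data, {{ predicted }})
  y <- dplyr::pull(data, {{ observed }})
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in pairs", call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in predicted or observed values", call. = FALSE)
  }
  fit <- lm(y ~ x)
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  tibble(
    n = length(x),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r = unname(ct$estimate),
    r_p_value = ct$p.value
  )
}

#' One-sample t test
#'
#' Tests whether the mean of `values` differs from a hypothesized value
#' (used to compare observed PK parameters across animals with the single
#' model-predicted value). Two-sided; `df = n - 1`.
#'
#' @param values numeric vector, `n >= 2`, non-zero SD.
#' @param mu hypothesized mean.
#' @return one-row tibble: `n`, `mean`, `t`, `df`, `p_value`.
#' @export
one_sample_t <- function(values, mu) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (sd(values) == 0) stop("zero standard deviation", call. = FALSE)
  ht <- t.test(values, mu = mu)
  tibble(n = length(values), mean = mean(values),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Two-sample t test
#'
#' Two-sided comparison of two groups' PK parameters; classic
#' pooled-variance test by default, Welch via `pooled = FALSE`.
#'
#' @param x,y numeric vectors, each `n >= 2`.
#' @param pooled assume equal variances (pooled) or not (Welch).
#' @return one-row tibble: `n_x`, `n_y`, `mean_x`, `mean_y`, `t`, `df`,
#'   `p_value`.
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (var(x) == 0 && var(y) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  ht <- t.test(x, y, var.equal = pooled)
  tibble(n_x = length(x), n_y = length(y),
         mean_x = mean(x), mean_y = mean(y),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Pair observed time-point means with model predictions
#'
#' Averages the observed concentrations at each sampling time (censored
#' points excluded) and joins the model prediction at the same clock
#' time, yielding the pairs scored by [eval_pred_obs()].
#'
#' @param sim a `pk_sim` from [pk_simulate()] covering the observation
#'   times.
#' @param observations multi-subject observations table.
#' @param geometric average observations geometrically.
#' @return tibble `time_h`, `predicted`, `observed`, `n`.
#' @export
pair_pred_obs <- function(sim, observations, geometric = FALSE) {
  m <- mean_profile(observations, geometric = geometric)
  miss <- setdiff(m$time_h, sim$time_h)
  if (length(miss)) {
    stop("simulation lacks observation time(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble(
    time_h = m$time_h,
    predicted = sim$C_int_ug_per_kg[match(m$time_h, sim$time_h)],
    observed = m$conc_ug_per_kg,
    n = m$n
  )
}
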