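truth <- mt_params(BW = 27)
reg40 <- dose_regimen(40, 0, 27)

noise_free_obs <- function(params = truth, regimen = reg40,
                           times = experiment1_schedule()) {
  sim <- pk_simulate(params, regimen, times)
  ct_profile(1L, sim$time_h, sim$C_int_ug_per_kg)
}

test_that("NLL is minimized at the generating parameters for exact data", {
  obs <- noise_free_obs()
  nll_truth <- pk_nll(truth, obs, reg40)
  for (cand in list(update_params(truth, list(k_a = truth$k_a * 1.3)),
                    update_params(truth, list(k_st = truth$k_st * 0.6)),
                    update_params(truth, list(k_bi = truth$k_bi * 2)))) {
    expect_gt(pk_nll(cand, obs, reg40), nll_truth)
  }
})

test_that("NLL penalises rather than NaNs on degenerate predictions", {
  obs <- noise_free_obs()
  expect_error(pk_nll(truth, obs[obs$blq, ], reg40), "no uncensored")
  # absurd parameters can zero out the prediction; the NLL must stay finite
  dead <- update_params(truth, list(k_st = 1e-4, k_a = 1e-4))
  expect_true(is.finite(pk_nll(dead, obs, reg40)))
})

test_that("the generator beats a rival parameter set in almost all replicates", {
  rival <- update_params(truth, list(k_a = truth$k_a * 2))
  wins <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    spec <- cohort_spec(n_subjects = 2, iiv_cv = c(k_a = 0),
                        residual_cv = 0.2, seed = s)
    obs <- generate_observations(sample_cohort(spec, truth))
    # score the shared-BW mean profile against both candidates
    m <- mean_profile(obs, geometric = TRUE)
    wins <- wins + (pk_nll(truth, m, reg40) < pk_nll(rival, m, reg40))
  }
  expect_gte(wins, 0.95 * n_rep)
})

test_that("one-parameter recovery from noisy cohorts lands within 5%", {
  spec <- cohort_spec(n_subjects = 6, iiv_cv = c(k_a = 0),
                      residual_cv = 0.2, seed = 11)
  obs <- generate_observations(sample_cohort(spec, truth))
  fit <- pk_fit(obs, reg40, start = update_params(truth, list(k_a = 0.3)),
                fit = "k_a", restarts = 0)
  expect_lt(abs(fit$params$k_a / truth$k_a - 1), 0.05)
  expect_equal(fit$estimates$start, 0.3)
})

test_that("three-parameter batch recovery has median error within 15%", {
  errs <- purrr::map(1:10, function(s) {
    spec <- cohort_spec(n_subjects = 6, iiv_cv = c(k_a = 0),
                        residual_cv = 0.2, seed = 100 + s)
    obs <- generate_observations(sample_cohort(spec, truth))
    start <- update_params(truth, list(k_st = 0.4, k_a = 0.4, k_bi = 0.02))
    fit <- pk_fit(obs, reg40, start = start, fit = c("k_st", "k_a", "k_bi"),
                  restarts = 1, seed = s)
    abs(unlist(fit$params[c("k_st", "k_a", "k_bi")]) /
          unlist(truth[c("k_st", "k_a", "k_bi")]) - 1)
  })
  med <- apply(do.call(rbind, errs), 2, stats::median)
  expect_true(all(med < 0.15))
})

test_that("starting at the truth stays at the truth", {
  obs <- noise_free_obs()
  fit <- pk_fit(obs, reg40, start = truth, fit = c("k_st", "k_a"),
                restarts = 0)
  expect_lt(abs(fit$params$k_st / truth$k_st - 1), 1e-6)
  expect_lt(abs(fit$params$k_a / truth$k_a - 1), 1e-6)
})

test_that("fitted parameters never leave their bounds", {
  spec <- cohort_spec(n_subjects = 3, residual_cv = 0.5, seed = 5)
  obs <- generate_observations(sample_cohort(spec, truth))
  fit <- pk_fit(obs, reg40, start = mt_params_start(),
                fit = c("k_a", "F"),
                lower = list(k_a = 0.2, F = 0.5),
                upper = list(k_a = 0.9, F = 0.9), restarts = 1)
  est <- fit$estimates
  expect_true(all(est$estimate >= est$lower & est$estimate <= est$upper))
  expect_error(pk_fit(obs, reg40, fit = "BW"), "cannot fit")
  expect_error(pk_fit(obs, reg40, fit = "k_a",
                      lower = list(k_a = 2), upper = list(k_a = 1)),
               "bounds")
})

test_that("batched optimization carries estimates between batches", {
  obs <- noise_free_obs()
  start <- update_params(truth, list(k_st = 0.5, k_bi = 0.02))
  # two coordinate-descent cycles over the batches
  fit <- pk_fit_batches(obs, reg40, start = start,
                        batches = list("k_st", "k_bi", "k_st", "k_bi"),
                        restarts = 0)
  expect_length(fit$batch_history, 4)
  expect_lt(abs(fit$params$k_st / truth$k_st - 1), 0.05)
  expect_lt(abs(fit$params$k_bi / truth$k_bi - 1), 0.05)
})

test_that("tidy and glance summarise a fit", {
  obs <- noise_free_obs()
  fit <- pk_fit(obs, reg40, start = truth, fit = "k_a", restarts = 0)
  td <- tidy(fit)
  expect_named(td, c("term", "start", "estimate", "lower", "upper"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(obs))
  expect_equal(gl$convergence, 0)
})
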