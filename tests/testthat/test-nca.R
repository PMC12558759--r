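# dense monoexponential and one-compartment fixtures used repeatedly
mono_profile <- function(c0 = 100, k = 0.5, times = seq(0, 12, by = 0.05)) {
  ct_profile(1L, times, c0 * exp(-k * times))
}

test_that("cmax/tmax read the curve directly, first occurrence on ties", {
  p <- ct_profile(1L, c(1, 2, 3), c(5, 9, 4))
  expect_equal(nca_cmax_tmax(p), tibble::tibble(cmax_ug_per_L = 9,
                                                tmax_h = 2))
  const <- ct_profile(1L, c(1, 2, 3), c(7, 7, 7))
  expect_equal(nca_cmax_tmax(const)$tmax_h, 1)
  censored <- ct_profile(1L, c(1, 2), c(2, 2), blq = c(TRUE, TRUE))
  expect_error(nca_cmax_tmax(censored), "no uncensored")
})

test_that("trapezoidal AUC matches hand geometry and closed forms", {
  tri <- ct_profile(1L, c(0, 1, 2), c(0, 10, 0))
  expect_equal(nca_auc(tri, t_end = 2), 10)
  flat <- ct_profile(1L, c(0, 1, 2), c(10, 10, 10))
  expect_equal(nca_auc(flat, t_end = 2), 20)
  # dense exponential sampled on [0, 12]: integral 200 (1 - e^-6)
  dtimes <- seq(0, 12, by = 0.05)
  dense <- ct_profile(1L, dtimes, 100 * exp(-0.5 * dtimes))
  expect_equal(nca_auc(dense, t_end = 12), 200 * (1 - exp(-6)),
               tolerance = 1e-3)
  expect_error(nca_auc(tri, t_end = 0.5), "fewer than two")
})

test_that("AUC is additive over adjacent intervals", {
  set.seed(7)
  prof <- ct_profile(1L, sort(runif(20, 0, 48)), runif(20, 1, 100))
  for (cut in prof$time_h[c(5, 10, 15)]) {
    expect_equal(
      nca_auc(prof, t_end = cut) +
        nca_auc(prof, t_start = cut, t_end = max(prof$time_h)),
      nca_auc(prof, t_end = max(prof$time_h))
    )
  }
})

test_that("terminal slope is exact on log-linear data", {
  tt <- c(24, 36, 48, 72, 120)
  prof <- ct_profile(1L, c(1, tt), c(60, 50 * exp(-0.1 * tt)))
  lz <- nca_lambda_z(prof)
  expect_equal(lz$lambda_z, 0.1, tolerance = 1e-9)
  expect_equal(lz$r_squared, 1, tolerance = 1e-12)
})

test_that("suffix search isolates the slow phase of a bi-exponential", {
  tt <- experiment1_schedule()
  conc <- 1000 * exp(-0.5 * tt) + 10 * exp(-0.01 * tt)
  prof <- ct_profile(1L, tt, conc)
  lz <- nca_lambda_z(prof)
  expect_equal(lz$lambda_z, 0.01, tolerance = 0.1)
  # oracle: fit restricted to t >= 72 where the slow phase dominates
  late <- tt[tt >= 72]
  fit <- lm(log(1000 * exp(-0.5 * late) + 10 * exp(-0.01 * late)) ~ late)
  expect_equal(lz$lambda_z, -unname(coef(fit)[2]), tolerance = 0.02)
})

test_that("terminal slope needs three points after the peak", {
  prof <- ct_profile(1L, c(1, 2, 3, 4), c(5, 9, 4, 2))
  expect_error(nca_lambda_z(prof), "at least 3")
})

test_that("lambda_z is invariant to uniform concentration scaling", {
  tt <- experiment1_schedule()
  conc <- 500 * exp(-0.3 * tt) + 5 * exp(-0.02 * tt)
  a <- nca_lambda_z(ct_profile(1L, tt, conc))
  b <- nca_lambda_z(ct_profile(1L, tt, conc * 1000))
  expect_equal(a$lambda_z, b$lambda_z, tolerance = 1e-12)
  expect_equal(a$points, b$points)
})

test_that("half-life uses the 0.693 convention exactly", {
  expect_equal(nca_half_life(0.0693), 10)
  expect_equal(nca_half_life(0.693), 1)
  expect_equal(nca_half_life(0.1), 6.93)
  expect_error(nca_half_life(0), "positive")
  # monoexponential: t_half * lambda_z = 0.693 by construction
  lz <- nca_lambda_z(mono_profile(100, 0.2, times = seq(0, 40, by = 1)))
  expect_equal(nca_half_life(lz$lambda_z) * lz$lambda_z, 0.693)
})

test_that("full NCA matches one-compartment closed forms within 1%", {
  # ka = 1/h, ke = 0.1/h, F Dose/V = 100 ug/L with V/F = 1 L/kg
  ka <- 1
  ke <- 0.1
  times <- seq(0.1, 120, by = 0.1)
  prof <- ct_profile(1L, times, oracle_onecomp_oral(times, 100, ka, ke))
  res <- nca(prof, dose_mg_per_kg = 0.1, t_end = 120)  # 100 ug/kg
  expect_equal(res$lambda_z, ke, tolerance = 0.01)
  expect_equal(res$cl_f_L_h_kg, ke * 1, tolerance = 0.01)
  expect_equal(res$v_f_L_kg, 1, tolerance = 0.01)
  expect_equal(res$mrt_h, 1 / ke + 1 / ka, tolerance = 0.01)
})

test_that("MRT of a monoexponential decline is 1/k", {
  k <- 0.25
  prof <- mono_profile(200, k, times = seq(0, 60, by = 0.05))
  res <- nca(prof, dose_mg_per_kg = 1, t_end = 60)
  expect_equal(res$mrt_h, 1 / k, tolerance = 0.01)
})

test_that("NCA is homogeneous: doubling concentrations halves CL/F", {
  tt <- experiment1_schedule()
  conc <- 800 * exp(-0.4 * tt) + 20 * exp(-0.03 * tt)
  r1 <- nca(ct_profile(1L, tt, conc), dose_mg_per_kg = 40)
  r2 <- nca(ct_profile(1L, tt, 2 * conc), dose_mg_per_kg = 40)
  expect_equal(r2$cmax_ug_per_L, 2 * r1$cmax_ug_per_L)
  expect_equal(r2$auc_0_inf, 2 * r1$auc_0_inf, tolerance = 1e-12)
  expect_equal(r2$cl_f_L_h_kg, r1$cl_f_L_h_kg / 2, tolerance = 1e-12)
})

test_that("censored handling: pre-peak BLQ is zero, post-peak BLQ dropped", {
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
  conc <- c(2, 40, 100, 80, 40, 10, 4, 2)
  blq <- c(TRUE, rep(FALSE, 6), TRUE)
  prof <- ct_profile(1L, tt, conc, blq)
  # AUC first segment contributes 0.25/2*(0+40) = 5, last (censored) none
  full <- nca_auc(prof, t_end = 24)
  manual <- sum(diff(tt[2:7]) * (conc[2:6] + conc[3:7]) / 2) +
    0.25 / 2 * (0 + 40)
  expect_equal(full, manual)
  lz <- nca_lambda_z(prof)
  expect_false(24 %in% lz$points)
})

test_that("per-subject NCA returns one row per pig", {
  tt <- experiment1_schedule()
  obs <- dplyr::bind_rows(purrr::map(1:3, function(i) {
    ct_profile(i, tt, i * (900 * exp(-0.4 * tt) + 15 * exp(-0.025 * tt)))
  }))
  res <- nca_by_subject(obs, dose_mg_per_kg = 40)
  expect_equal(nrow(res), 3)
  expect_equal(res$subject_id, 1:3)
  expect_equal(res$lambda_z, rep(res$lambda_z[1], 3), tolerance = 1e-10)
})

test_that("mean_profile averages uncensored points per time", {
  obs <- dplyr::bind_rows(
    ct_profile(1L, c(1, 2), c(10, 4)),
    ct_profile(2L, c(1, 2), c(30, 2), blq = c(FALSE, TRUE))
  )
  m <- mean_profile(obs)
  expect_equal(m$conc_ug_per_kg, c(20, 4))
  expect_equal(m$n, c(2, 1))
  g <- mean_profile(obs, geometric = TRUE)
  expect_equal(g$conc_ug_per_kg[1], sqrt(10 * 30))
})
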