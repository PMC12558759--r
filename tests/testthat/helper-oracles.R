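# Independent oracles used across the test files. These are deliberately
# written from first principles (literal mass-balance transcriptions,
# closed forms, naive fixed-step integration, textbook statistics) and
# never call the package's own computational paths.

# Literal term-by-term transcription of the compartmental mass-balance
# equations, evaluated symbolically on a plain list of amounts. `ca_free`
# substitutes the free blood concentration for the arterial driving
# concentration; `f_absorb` scales the absorption flux into blood.
oracle_rhs <- function(A, p, ca_free = TRUE, f_absorb = 1) {
  V_int <- p$Vc_int * p$BW
  V_l <- p$Vc_l * p$BW
  V_b <- p$Vc_b * p$BW
  V_ot <- p$Vc_ot * p$BW
  Q_l <- p$Qc_l * p$Qcar * p$BW
  Q_ot <- p$Qc_ot * p$Qcar * p$BW
  Q_tot <- Q_l + Q_ot
  C_b <- A$A_b / V_b
  C_l <- A$A_l / V_l
  C_ot <- A$A_ot / V_ot
  Ca <- if (ca_free) C_b * (1 - p$Pb) else C_b

  list(
    A_st = -p$k_st * A$A_st,
    A_int = p$k_st * A$A_st + A$A_l * p$k_bi -
      A$A_int * p$k_a - A$A_int * p$k_e,
    A_l = Q_l * (Ca - C_l / p$P_l) - A$A_l * p$k_bi,
    A_ot = Q_ot * (Ca - C_ot / p$P_ot) - Ca * p$Cl_renal * p$BW,
    A_b = f_absorb * A$A_int * p$k_a + Q_l * (C_l / p$P_l) +
      Q_ot * (C_ot / p$P_ot) - Q_tot * C_b * (1 - p$Pb),
    A_feces = p$k_e * A$A_int,
    A_urine = Ca * p$Cl_renal * p$BW,
    A_unabsorbed = (1 - f_absorb) * p$k_a * A$A_int
  )
}

# Naive fixed-step classical RK4 over the five compartment amounts,
# driven by oracle_rhs. depot0 is the initial stomach amount (ug).
oracle_rk4 <- function(p, depot0, t_grid, dt = 0.001, ca_free = TRUE,
                       f_absorb = 1) {
  deriv <- function(A) {
    d <- oracle_rhs(
      list(A_st = A[1], A_int = A[2], A_l = A[3], A_ot = A[4], A_b = A[5]),
      p, ca_free = ca_free, f_absorb = f_absorb
    )
    c(d$A_st, d$A_int, d$A_l, d$A_ot, d$A_b)
  }
  A <- c(depot0, 0, 0, 0, 0)
  t <- 0
  out_t <- numeric(length(t_grid))
  out_aint <- numeric(length(t_grid))
  k <- 1
  t_end <- max(t_grid)
  eps <- dt / 2
  while (k <= length(t_grid) && t_grid[k] <= eps) {
    out_t[k] <- t
    out_aint[k] <- A[2]
    k <- k + 1
  }
  nsteps <- round(t_end / dt)
  for (i in seq_len(nsteps)) {
    k1 <- deriv(A)
    k2 <- deriv(A + dt / 2 * k1)
    k3 <- deriv(A + dt / 2 * k2)
    k4 <- deriv(A + dt * k3)
    A <- A + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- i * dt
    while (k <= length(t_grid) && t_grid[k] <= t + eps) {
      out_t[k] <- t
      out_aint[k] <- A[2]
      k <- k + 1
    }
  }
  data.frame(time_h = t_grid, C_int = out_aint / (p$Vc_int * p$BW))
}

# Bateman two-step cascade: depot D emptying at k1 into a compartment
# eliminating at k2.
oracle_bateman <- function(t, D, k1, k2) {
  D * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
}

# One-compartment oral concentration curve, dose scaled so that
# F*Dose/V = c0.
oracle_onecomp_oral <- function(t, c0, ka, ke) {
  c0 * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
}

# Textbook Pearson correlation via the covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = tt, p = 2 * stats::pt(-abs(tt), df = n - 2),
       slope = sxy / sxx, intercept = mean(y) - sxy / sxx * mean(x))
}

# Textbook one-sample t.
oracle_t1 <- function(x, mu) {
  n <- length(x)
  tt <- (mean(x) - mu) / (stats::sd(x) / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), df = n - 1))
}

# Textbook pooled two-sample t.
oracle_t2 <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, df = nx + ny - 2,
       p = 2 * stats::pt(-abs(tt), df = nx + ny - 2))
}

# Dense-grid counting estimate of percent time above a threshold.
oracle_pct_above <- function(time_h, conc, thr_ug_per_L) {
  mean(conc > thr_ug_per_L) * 100
}

# Convenience: a parameter set with every exchange shut off except those
# listed, for single-term balance checks.
params_only <- function(..., BW = 27) {
  base <- list(Qcar = 0, PCV = 0, Qc_l = 0.3, Qc_ot = 0.7,
               Vc_int = 0.0136733, Vc_l = 0.0294, Vc_b = 0.06,
               Vc_ot = 0.8969267, k_st = 0, k_a = 0, F = 1,
               P_l = 1, P_ot = 1, k_e = 0, k_bi = 0, Pb = 0,
               Cl_renal = 0, BW = BW)
  args <- utils::modifyList(base, list(...))
  args$BW <- BW
  do.call(mt_params, args)
}
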