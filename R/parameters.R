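#' Model parameter sets
#'
#' `mt_params()` builds the full parameter set of the minimal pig PBPK
#' model: physiological constants (cardiac output, organ blood-flow and
#' volume fractions), compound constants (gastric emptying, absorption,
#' excretion rates, partition coefficients, bioavailability, protein
#' binding, renal clearance) and body weight. Defaults are the optimized
#' values of the published pig model; `mt_params_start()` carries the
#' literature starting values used before optimization.
#'
#' @param ... named overrides of individual parameters (see Details).
#' @param BW body weight in kg (defaults to 27, the middle of the
#'   24.3--31.1 kg range of the single-dose study animals).
#'
#' @details Parameters and units:
#' \describe{
#'   \item{Qcar}{cardiac output, L/(h.kg BW)}
#'   \item{PCV}{hematocrit, fraction (carried for completeness; it enters
#'     no model equation)}
#'   \item{Qc_l, Qc_ot}{liver / other-organ blood flows, fractions of
#'     cardiac output (must sum to 1)}
#'   \item{Vc_int, Vc_l, Vc_b, Vc_ot}{intestinal-content, liver, blood and
#'     other-organ volumes, fractions of body weight (sum at most 1)}
#'   \item{k_st}{first-order gastric-emptying rate, 1/h}
#'   \item{k_a}{first-order intestinal absorption rate, 1/h}
#'   \item{F}{oral bioavailability, fraction}
#'   \item{P_l, P_ot}{tissue-to-blood partition coefficients}
#'   \item{k_e}{first-order fecal excretion rate, 1/h}
#'   \item{k_bi}{first-order biliary excretion rate (liver to lumen), 1/h}
#'   \item{Pb}{plasma protein binding, fraction; (1 - Pb) is the free
#'     fraction}
#'   \item{Cl_renal}{renal clearance, L/(h.kg BW)}
#'   \item{BW}{body weight, kg}
#' }
#'
#' @return an object of class `mt_params` (a validated named list).
#' @examples
#' p <- mt_params(BW = 27)
#' p$k_a
#' derived_params(p)
#' @export
mt_params <- function(..., BW = 27) {
  defaults <- list(
    Qcar = 4.944, PCV = 0.333, Qc_l = 0.3, Qc_ot = 0.7,
    Vc_int = 0.0136733, Vc_l = 0.0294, Vc_b = 0.06, Vc_ot = 0.8969267,
    k_st = 0.8544925, k_a = 0.8555538, F = 0.7925891,
    P_l = 2.936615, P_ot = 11.33514,
    k_e = 0.007358172, k_bi = 0.05834594, Pb = 0.319,
    Cl_renal = 0.2805897, BW = BW
  )
  new_mt_params(defaults, list(...))
}

#' @rdname mt_params
#' @export
mt_params_start <- function(..., BW = 27) {
  defaults <- list(
    Qcar = 4.944, PCV = 0.333, Qc_l = 0.3, Qc_ot = 0.7,
    Vc_int = 0.01, Vc_l = 0.0294, Vc_b = 0.06, Vc_ot = 0.9006,
    k_st = 0.1, k_a = 0.3, F = 0.171,
    P_l = 5.5, P_ot = 5,
    k_e = 0.01, k_bi = 0.01, Pb = 0.3,
    Cl_renal = 1.182, BW = BW
  )
  new_mt_params(defaults, list(...))
}

param_names <- function() {
  c("Qcar", "PCV", "Qc_l", "Qc_ot", "Vc_int", "Vc_l", "Vc_b", "Vc_ot",
    "k_st", "k_a", "F", "P_l", "P_ot", "k_e", "k_bi", "Pb", "Cl_renal",
    "BW")
}

new_mt_params <- function(defaults, overrides) {
  if (length(overrides)) {
    bad <- setdiff(names(overrides), param_names())
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    defaults <- modifyList(defaults, overrides)
  }
  p <- structure(defaults[param_names()], class = "mt_params")
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks non-negativity of all rates, flows and clearances, that
#' fractional quantities lie in \[0, 1\], that the organ blood-flow
#' fractions sum to one, and that the volume fractions sum to at most one
#' (the remainder being non-compartmental body mass).
#'
#' @param p an `mt_params` object or named list with the same fields.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  need <- setdiff(param_names(), names(p))
  if (length(need)) {
    stop("missing parameter(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(p[param_names()])
  if (any(!is.finite(vals))) stop("non-finite parameter value", call. = FALSE)
  if (any(vals < 0)) {
    stop("negative parameter(s): ",
         paste(param_names()[vals < 0], collapse = ", "), call. = FALSE)
  }
  fr <- c("PCV", "Qc_l", "Qc_ot", "Vc_int", "Vc_l", "Vc_b", "Vc_ot",
          "F", "Pb")
  over <- fr[unlist(p[fr]) > 1]
  if (length(over)) {
    stop("fractional parameter(s) above 1: ", paste(over, collapse = ", "),
         call. = FALSE)
  }
  if (abs(p$Qc_l + p$Qc_ot - 1) > 1e-9) {
    stop("Qc_l + Qc_ot must equal 1 (got ", p$Qc_l + p$Qc_ot, ")",
         call. = FALSE)
  }
  vsum <- p$Vc_int + p$Vc_l + p$Vc_b + p$Vc_ot
  if (vsum > 1 + 1e-9) {
    stop("volume fractions sum to ", vsum, " (> 1)", call. = FALSE)
  }
  if (p$BW <= 0) stop("BW must be positive", call. = FALSE)
  invisible(p)
}

#' Derived absolute flows and volumes
#'
#' Converts the fractional physiological parameters into absolute
#' quantities under the unit-density convention (1 kg body mass occupies
#' 1 L): compartment volumes `V_* = Vc_* x BW` in litres, blood flows
#' `Q_l = Qc_l x Qcar x BW` and `Q_ot` in L/h, total flow
#' `Q_tot = Q_l + Q_ot`, and absolute renal clearance
#' `Cl_renal x BW` in L/h.
#'
#' @param p an `mt_params` object.
#' @return a one-row tibble of derived quantities.
#' @export
derived_params <- function(p) {
  validate_params(p)
  tibble(
    V_int = p$Vc_int * p$BW,
    V_l = p$Vc_l * p$BW,
    V_b = p$Vc_b * p$BW,
    V_ot = p$Vc_ot * p$BW,
    Q_l = p$Qc_l * p$Qcar * p$BW,
    Q_ot = p$Qc_ot * p$Qcar * p$BW,
    Q_tot = p$Qcar * p$BW,
    Cl_renal_abs = p$Cl_renal * p$BW
  )
}

#' @export
print.mt_params <- function(x, ...) {
  cat("<mt_params> pig PBPK parameter set (BW =", x$BW, "kg)\n")
  df <- tibble(parameter = param_names(),
               value = unlist(x[param_names()]))
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

#' @export
as_tibble.mt_params <- function(x, ...) {
  as_tibble(as.list(unclass(x)))
}

#' Rebuild a parameter set from a one-row data frame
#'
#' The inverse of `as_tibble.mt_params()`; used when iterating over the
#' rows of a synthetic cohort (see [sample_cohort()]). Extra columns
#' (e.g. `subject_id`, `bw_kg`) are ignored.
#'
#' @param row a one-row data frame carrying all parameter columns.
#' @return an `mt_params` object.
#' @export
params_from_row <- function(row) {
  row <- as.list(row)
  if (!is.null(row$bw_kg) && is.null(row$BW)) row$BW <- row$bw_kg
  new_mt_params(row[param_names()], list())
}

#' Update parameters, optionally rebalancing closure fractions
#'
#' Returns a copy of `p` with the named values replaced. With
#' `rebalance = TRUE` the balancing fractions are recomputed so the
#' physiological closure holds: `Qc_ot = 1 - Qc_l` and
#' `Vc_ot = 1 - (Vc_int + Vc_l + Vc_b)`, mirroring how the published
#' parameter table obtains both "by calculation".
#'
#' @param p an `mt_params` object.
#' @param values named list/vector of new parameter values.
#' @param rebalance recompute `Qc_ot` and `Vc_ot` closure terms.
#' @return an `mt_params` object.
#' @export
update_params <- function(p, values, rebalance = FALSE) {
  q <- modifyList(as.list(unclass(p)), as.list(values))
  if (rebalance) {
    q$Qc_ot <- 1 - q$Qc_l
    q$Vc_ot <- 1 - (q$Vc_int + q$Vc_l + q$Vc_b)
  }
  new_mt_params(q, list())
}
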