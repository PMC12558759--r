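#' Read and write parameter configuration files
#'
#' Plain-text `key: value` files mirroring the model parameter symbols
#' (`Qcar`, `PCV`, `Qc_l`, `Qc_ot`, `Vc_int`, `Vc_l`, `Vc_b`, `Vc_ot`,
#' `k_st`, `k_a`, `F`, `P_l`, `P_ot`, `k_e`, `k_bi`, `Pb`, `Cl_renal`,
#' `BW`). Lines starting with `#` and blank lines are ignored. Two files
#' ship with the package: `params_optimized.txt` (the optimized pig
#' model) and `params_starting.txt` (literature starting values); see
#' [mt_params_file()].
#'
#' @param path file path.
#' @return [read_params()] returns an `mt_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  bad <- !grepl("^[A-Za-z_][A-Za-z0-9_]*\\s*:", lines)
  if (any(bad)) {
    stop("malformed line ", which(bad)[1], " in ", path, ": '",
         lines[bad][1], "' (expected 'key: value')", call. = FALSE)
  }
  keys <- trimws(sub(":.*$", "", lines))
  vals <- suppressWarnings(as.numeric(trimws(sub("^[^:]*:", "", lines))))
  if (any(is.na(vals))) {
    stop("non-numeric value for key '", keys[is.na(vals)][1], "' in ",
         path, call. = FALSE)
  }
  new_mt_params(as.list(setNames(vals, keys)), list())
}

#' @rdname read_params
#' @param params an `mt_params` object.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  writeLines(
    sprintf("%s: %.10g", param_names(), unlist(params[param_names()])),
    path
  )
  invisible(path)
}

#' Packaged parameter files
#'
#' @param which `"optimized"` or `"starting"`.
#' @return path to the installed configuration file.
#' @export
mt_params_file <- function(which = c("optimized", "starting")) {
  which <- match.arg(which)
  system.file("extdata", paste0("params_", which, ".txt"),
              package = "matrinepk", mustWork = TRUE)
}

#' Read and write observation tables
#'
#' Comma-separated, UTF-8, header row mandatory: `subject_id`, `time_h`,
#' `conc_ug_per_kg`, `blq` (logical or 0/1).
#'
#' @param path file path.
#' @return a validated observations tibble.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "time_h", "conc_ug_per_kg", "blq")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop(path, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out$blq <- as.logical(out$blq)
  check_profile(out)
  out
}

#' @rdname read_profiles
#' @param observations observations tibble.
#' @export
write_profiles <- function(observations, path) {
  check_profile(observations)
  readr::write_csv(observations, path)
  invisible(path)
}

#' Write a simulation result as delimited text
#'
#' Columns: `time_h`, compartment amounts, `C_int_ug_per_kg`,
#' `C_b_ug_per_L` and the mass-balance `residual`.
#'
#' @param sim a `pk_sim`.
#' @param path file path.
#' @export
write_sim <- function(sim, path) {
  stopifnot(inherits(sim, "pk_sim"))
  readr::write_csv(
    select(as_tibble(sim), "time_h", "A_st", "A_int", "A_l", "A_ot",
           "A_b", "C_int_ug_per_kg", "C_b_ug_per_L", "residual"),
    path
  )
  invisible(path)
}
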