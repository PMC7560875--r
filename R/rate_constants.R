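#' Rate constants of the fuel-driven reaction cycle
#'
#' The five first- and second-order rate constants of the carbodiimide
#' reaction cycle: direct fuel hydrolysis (`k0`), activation of the precursor
#' by fuel to the O-acylisourea (`k1`), conversion of the O-acylisourea to the
#' anhydride (`k2`), futile hydrolysis of the O-acylisourea back to the
#' precursor (`k3`), and hydrolysis of the anhydride back to the precursor
#' (`k4`, the deactivation).
#'
#' Units are minutes and millimolar throughout: `k0`, `k2`, `k3`, `k4` are
#' first-order (per minute); `k1` is second-order (per mM per minute).
#'
#' @param k0 First-order rate of direct fuel (EDC) hydrolysis, per minute.
#' @param k1 Second-order rate of precursor activation by fuel, per mM per
#'   minute.
#' @param k2 First-order rate of O-acylisourea to anhydride conversion, per
#'   minute.
#' @param k3 First-order rate of O-acylisourea hydrolysis back to the
#'   precursor, per minute.
#' @param k4 First-order rate of anhydride hydrolysis (deactivation), per
#'   minute.
#'
#' @return An object of class `rate_constants`: a named list of the five
#'   non-negative, finite rates.
#' @seealso [default_rate_constants()] for the packaged calibrated values.
#' @export
#' @examples
#' rate_constants(0.08, 0.04, 1.3, 6.3, 0.09)
rate_constants <- function(k0, k1, k2, k3, k4) {
  k <- list(k0 = k0, k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  vals <- unlist(k)
  if (length(vals) != 5L || !is.numeric(vals)) {
    stop("all five rate constants must be single numeric values", call. = FALSE)
  }
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rate constants must be finite and >= 0", call. = FALSE)
  }
  structure(lapply(k, as.numeric), class = "rate_constants")
}

#' Packaged default rate constants
#'
#' Reads the rate-constant configuration shipped with the package
#' (`extdata/rate_constants.json`). These values were calibrated with
#' [fit_rate_constants()]-style least squares against the observables of the
#' standard experimental conditions (23 mM precursor, 200 mM MES pH 5.3,
#' 25 degrees C); see the methods vignette for the calibration protocol. They
#' are configuration, not constants of nature: pass your own
#' [rate_constants()] anywhere the model is evaluated.
#'
#' @param path Optional path to an alternative JSON file with fields
#'   `k0` ... `k4`.
#' @return A [rate_constants()] object.
#' @export
default_rate_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rate_constants.json", package = "fueldrops")
  }
  cfg <- jsonlite::read_json(path)
  rate_constants(cfg$k0, cfg$k1, cfg$k2, cfg$k3, cfg$k4)
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Reaction-cycle rate constants (mM, min):\n")
  cat(sprintf("  k0 = %.5g /min   (fuel hydrolysis)\n", x$k0))
  cat(sprintf("  k1 = %.5g /mM/min (activation)\n", x$k1))
  cat(sprintf("  k2 = %.5g /min   (intermediate -> anhydride)\n", x$k2))
  cat(sprintf("  k3 = %.5g /min   (intermediate hydrolysis)\n", x$k3))
  cat(sprintf("  k4 = %.5g /min   (anhydride deactivation)\n", x$k4))
  invisible(x)
}

as_rate_constants <- function(k) {
  if (inherits(k, "rate_constants")) return(k)
  k <- as.list(k)
  rate_constants(k$k0, k$k1, k$k2, k$k3, k$k4)
}

#' Experimental conditions of a reaction-cycle run
#'
#' @param F0 Initial fuel (EDC) concentration, mM.
#' @param P0 Initial precursor peptide concentration, mM (default 23, the
#'   standard condition).
#' @param U0 RNA concentration in uridine monomer units, mM (default 4.1).
#'   The RNA does not enter the kinetics; it is carried for phase analysis.
#' @param buffer Buffer descriptor (text).
#' @param temperature Temperature in degrees C.
#' @return An object of class `experiment_config`.
#' @export
#' @examples
#' experiment_config(F0 = 25)
experiment_config <- function(F0, P0 = 23, U0 = 4.1,
                              buffer = "200 mM MES pH 5.3",
                              temperature = 25) {
  stopifnot(is.numeric(F0), length(F0) == 1L, is.numeric(P0), is.numeric(U0))
  if (!is.finite(F0) || F0 < 0 || !is.finite(P0) || P0 < 0 || !is.finite(U0) || U0 < 0) {
    stop("F0, P0 and U0 must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(F0 = as.numeric(F0), P0 = as.numeric(P0), U0 = as.numeric(U0),
         buffer = buffer, temperature = temperature),
    class = "experiment_config"
  )
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "Experiment: %g mM fuel, %g mM precursor, %g mM RNA (monomer), %s, %g C\n",
    x$F0, x$P0, x$U0, x$buffer, x$temperature))
  invisible(x)
}
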