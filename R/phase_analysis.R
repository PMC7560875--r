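#' Phase boundaries of the droplet regime map
#'
#' Defaults encode the observed map at standard conditions: no droplets up
#' to 7.5 mM fuel at any RNA concentration, and a dynamic-to-metastable
#' boundary anchored at (1.4 mM RNA, 25 mM fuel) and (4.1 mM RNA, 40 mM
#' fuel), interpolated linearly and clamped outside the anchors.
#'
#' @param A_crit Critical anhydride concentration for coacervation, mM.
#' @param fuel_lower Fuel threshold below which no droplets form, mM
#'   (RNA-independent).
#' @param anchors Data frame with columns `rna_mM`, `fuel_mM`: the
#'   dynamic-to-metastable boundary anchor points.
#' @return An object of class `phase_boundaries`.
#' @export
phase_boundaries <- function(A_crit = 0.9, fuel_lower = 7.5,
                             anchors = data.frame(rna_mM = c(1.4, 4.1),
                                                  fuel_mM = c(25, 40))) {
  stopifnot(A_crit > 0, all(c("rna_mM", "fuel_mM") %in% names(anchors)))
  if (any(anchors$fuel_mM <= fuel_lower)) {
    stop("boundary fuel values must exceed the lower threshold", call. = FALSE)
  }
  structure(list(A_crit = A_crit, fuel_lower = fuel_lower,
                 anchors = anchors[order(anchors$rna_mM), ]),
            class = "phase_boundaries")
}

#' Critical coacervation concentration implied by a fuel threshold
#'
#' The peak anhydride concentration reached when the cycle is fuelled at
#' the turbidity-onset fuel concentration: the concentration of product at
#' which droplets just begin to form.
#'
#' @param threshold_fuel Fuel concentration at the turbidity onset, mM.
#' @param config Base [experiment_config()]; its `F0` is replaced by
#'   `threshold_fuel`.
#' @param k [rate_constants()].
#' @param t_end Integration span, minutes.
#' @return Peak anhydride concentration, mM.
#' @export
#' @examples
#' critical_concentration(7.5)
critical_concentration <- function(threshold_fuel,
                                   config = experiment_config(F0 = threshold_fuel),
                                   k = default_rate_constants(), t_end = 30) {
  stopifnot(threshold_fuel >= 0)
  config$F0 <- threshold_fuel
  if (threshold_fuel == 0) return(0)
  peak_anhydride(simulate_cycle(config, k, t_end = t_end))$A_peak
}

#' Minimal fuel concentration whose peak anhydride reaches a threshold
#'
#' Scans fuel upward for the smallest concentration (on a grid of the given
#' resolution) whose integrated cycle reaches a peak anhydride of at least
#' `A_crit`. A coarse scan brackets the onset, bisection refines it, and the
#' result is reported on the resolution grid.
#'
#' @param config Base [experiment_config()] (its `F0` is scanned).
#' @param k [rate_constants()].
#' @param A_crit Peak-anhydride threshold, mM.
#' @param resolution Grid resolution of the returned fuel value, mM.
#' @param fuel_max Upper end of the scan, mM.
#' @return Minimal fuel in mM (a multiple of `resolution`), or `NA` with a
#'   warning if the threshold is not reached by `fuel_max`.
#' @export
#' @examples
#' fuel_threshold_scan(A_crit = 0.9, resolution = 0.5)
fuel_threshold_scan <- function(config = experiment_config(F0 = 0),
                                k = default_rate_constants(),
                                A_crit = 0.9, resolution = 0.5,
                                fuel_max = 60) {
  stopifnot(resolution > 0)
  peak_at <- function(F0) {
    if (F0 <= 0) return(0)
    cfg <- config; cfg$F0 <- F0
    peak_anhydride(simulate_cycle(cfg, k, t_end = 25))$A_peak
  }
  if (A_crit <= 0) return(resolution)
  step <- max(resolution, fuel_max / 12)
  grid <- unique(c(seq(step, fuel_max, by = step), fuel_max))
  lo <- 0; hi <- NA_real_
  for (f in grid) {
    if (peak_at(f) >= A_crit) { hi <- f; break }
    lo <- f
  }
  if (is.na(hi)) {
    warning("peak anhydride never reaches A_crit within the scan range")
    return(NA_real_)
  }
  while (hi - lo > resolution / 4) {
    mid <- (lo + hi) / 2
    if (peak_at(mid) >= A_crit) hi <- mid else lo <- mid
  }
  cand <- ceiling(hi / resolution - 1e-9) * resolution
  while (peak_at(cand) < A_crit) cand <- cand + resolution
  cand
}

#' Classify a (fuel, RNA) condition into a droplet regime
#'
#' @param F0 Fuel concentration, mM.
#' @param U0 RNA concentration in monomer units, mM.
#' @param boundaries A [phase_boundaries()].
#' @return One of `"no_droplets"`, `"dynamic"`, `"metastable"`.
#' @export
#' @examples
#' classify_regime(25, 4.1)  # dynamic
#' classify_regime(60, 4.1)  # metastable
classify_regime <- function(F0, U0, boundaries = phase_boundaries()) {
  stopifnot(F0 >= 0, U0 >= 0, inherits(boundaries, "phase_boundaries"))
  if (F0 <= boundaries$fuel_lower) return("no_droplets")
  b <- boundaries$anchors
  fb <- stats::approx(b$rna_mM, b$fuel_mM, xout = U0, rule = 2)$y
  if (F0 >= fb) "metastable" else "dynamic"
}

#' Charge bookkeeping for the cation-to-anion ratio
#'
#' By default only the +3 anhydride product counts on the cation side (the
#' +1 precursor is excluded: it does not coacervate) and each RNA monomer
#' carries one negative charge.
#'
#' @param product Charge per anhydride product molecule.
#' @param precursor Charge per precursor molecule.
#' @param rna Charge per RNA monomer unit.
#' @param include_precursor Count the precursor on the cation side?
#' @return An object of class `charge_model`.
#' @export
charge_model <- function(product = 3L, precursor = 1L, rna = -1L,
                         include_precursor = FALSE) {
  stopifnot(product == round(product), precursor == round(precursor),
            rna == round(rna), rna < 0)
  structure(list(product = as.integer(product),
                 precursor = as.integer(precursor),
                 rna = as.integer(rna),
                 include_precursor = isTRUE(include_precursor)),
            class = "charge_model")
}

#' Two-phase mass balance of one species
#'
#' Splits a species' total concentration over the droplet and outer phases
#' from the measured total, the filtrate (outer-phase) concentration, and
#' the droplet volume fraction from centrifugation:
#' `droplet (sample basis) = total - filtrate * (1 - volume_fraction)` and
#' `in-droplet (M) = droplet / volume_fraction / 1000`.
#'
#' @param total Total concentration over both phases, mM (whole-sample
#'   basis).
#' @param filtrate Outer-phase concentration from the filtrate, mM.
#' @param volume_fraction Droplet volume fraction, strictly in (0, 1).
#' @param species Species label carried through to the result.
#' @return Object of class `mass_balance` (also a one-row data frame):
#'   columns `species`, `total_mM`, `outer_mM`, `droplet_mM` (sample basis),
#'   `volume_fraction`, `in_droplet_M`, `clamped`.
#' @export
#' @examples
#' mass_balance(total = 3.0, filtrate = 1.7, volume_fraction = 0.0014)
mass_balance <- function(total, filtrate, volume_fraction,
                         species = "anhydride") {
  stopifnot(is.numeric(total), total >= 0, is.numeric(filtrate), filtrate >= 0)
  if (!is.finite(volume_fraction) || volume_fraction <= 0 || volume_fraction >= 1) {
    stop("volume_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  droplet <- total - filtrate * (1 - volume_fraction)
  clamped <- FALSE
  if (droplet < 0) {
    warning("filtrate exceeds total; clamping droplet amount to 0 ",
            "(measurement noise)")
    droplet <- 0
    clamped <- TRUE
  }
  out <- data.frame(species = species, total_mM = total, outer_mM = filtrate,
                    droplet_mM = droplet, volume_fraction = volume_fraction,
                    in_droplet_M = droplet / volume_fraction / 1000,
                    clamped = clamped)
  class(out) <- c("mass_balance", "data.frame")
  out
}

#' Cation-to-anion charge ratio in the droplet phase
#'
#' @param product_mM Anhydride product in the droplet phase, mM on the
#'   whole-sample basis.
#' @param rna_mM RNA monomer units in the droplet phase, mM on the
#'   whole-sample basis (> 0).
#' @param charges A [charge_model()].
#' @param precursor_mM Precursor in the droplet phase (used only when the
#'   charge model includes it).
#' @return Dimensionless cation/anion ratio.
#' @export
charge_ratio <- function(product_mM, rna_mM, charges = charge_model(),
                         precursor_mM = 0) {
  stopifnot(inherits(charges, "charge_model"), product_mM >= 0)
  if (!is.finite(rna_mM) || rna_mM <= 0) {
    stop("rna_mM must be > 0", call. = FALSE)
  }
  cations <- charges$product * product_mM
  if (charges$include_precursor) cations <- cations + charges$precursor * precursor_mM
  cations / (abs(charges$rna) * rna_mM)
}

#' Turbidity trace
#'
#' @param time_min Sampling times, minutes, strictly increasing.
#' @param abs600 Blank-subtracted absorbance at 600 nm, a.u.
#' @return Object of class `turbidity_trace` (a data frame).
#' @export
turbidity_trace <- function(time_min, abs600) {
  stopifnot(length(time_min) == length(abs600))
  if (is.unsorted(time_min, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(abs600))) stop("absorbance must be finite", call. = FALSE)
  structure(data.frame(time_min = time_min, abs600 = abs600),
            class = c("turbidity_trace", "data.frame"))
}

#' Turbidity lifetime
#'
#' The time it takes, after fuel addition, for the blank-subtracted
#' absorbance at 600 nm to drop below the cutoff: the last interpolated
#' downward crossing following the trace maximum.
#'
#' @param trace A [turbidity_trace()].
#' @param cutoff Absorbance cutoff, a.u. (> 0; default 0.01).
#' @return Lifetime in minutes, or `NA` if the trace never exceeds the
#'   cutoff (no droplets).
#' @export
turbidity_lifetime <- function(trace, cutoff = 0.01) {
  stopifnot(inherits(trace, "turbidity_trace"))
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  a <- trace$abs600; t <- trace$time_min
  if (max(a) < cutoff) return(NA_real_)
  last_above <- max(which(a >= cutoff))
  if (last_above == length(a)) return(t[length(t)])
  cross_time(t, a, last_above, cutoff)
}
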