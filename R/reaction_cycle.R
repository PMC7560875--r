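#' Rate laws of the reaction cycle
#'
#' Evaluates the time derivatives of the five chemical species of the
#' fuel-driven cycle at a given state. Species: fuel `F` (EDC), precursor
#' peptide `P`, O-acylisourea intermediate `I`, anhydride product `A`, and
#' waste `W` (EDU), all in mM.
#'
#' The scheme is the standard carbodiimide cycle: the fuel hydrolyses
#' directly (`k0`) or condenses with the precursor (`k1`) to the
#' O-acylisourea, which either forms the anhydride (`k2`) or hydrolyses
#' futilely back to the precursor (`k3`); the anhydride hydrolyses back to
#' the precursor (`k4`). Peptide (`P + I + A`) and carbodiimide
#' (`F + I + W`) totals are conserved, so the derivative vector sums to zero
#' within each balance.
#'
#' @param state Named numeric vector with elements `F`, `P`, `I`, `A`, `W`
#'   (mM). All must be non-negative.
#' @param k A [rate_constants()] object.
#' @return Named numeric vector `(dF, dP, dI, dA, dW)` in mM per minute.
#' @export
#' @examples
#' k <- default_rate_constants()
#' cycle_derivatives(c(F = 25, P = 23, I = 0, A = 0, W = 0), k)
cycle_derivatives <- function(state, k) {
  k <- as_rate_constants(k)
  need <- c("F", "P", "I", "A", "W")
  if (!all(need %in% names(state))) {
    stop("state must be a named vector with elements F, P, I, A, W", call. = FALSE)
  }
  s <- as.numeric(state[need])
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("negative or non-finite concentration in state", call. = FALSE)
  }
  act <- k$k1 * s[1] * s[2]
  dF <- -k$k0 * s[1] - act
  dP <- -act + k$k3 * s[3] + k$k4 * s[4]
  dI <- act - (k$k2 + k$k3) * s[3]
  dA <- k$k2 * s[3] - k$k4 * s[4]
  dW <- k$k0 * s[1] + (k$k2 + k$k3) * s[3]
  c(dF = dF, dP = dP, dI = dI, dA = dA, dW = dW)
}

cycle_rhs <- function(t, y, parms) {
  act <- parms$k1 * y[1] * y[2]
  list(c(
    -parms$k0 * y[1] - act,
    -act + parms$k3 * y[3] + parms$k4 * y[4],
    act - (parms$k2 + parms$k3) * y[3],
    parms$k2 * y[3] - parms$k4 * y[4],
    parms$k0 * y[1] + (parms$k2 + parms$k3) * y[3]
  ))
}

#' Integrate the reaction cycle
#'
#' Integrates the well-mixed five-species ODE system from the initial state
#' `F = F0`, `P = P0`, `I = A = W = 0` with an adaptive stiff-capable solver
#' (`deSolve::ode`, lsoda). The returned time course is checked against the
#' two conservation laws (`P + I + A = P0`, `F + I + W = F0`) and the run
#' fails loudly if either is violated beyond a 1e-6 relative tolerance.
#'
#' @param config An [experiment_config()].
#' @param k A [rate_constants()] object (default: packaged constants).
#' @param t_end End of integration, minutes (> 0).
#' @param output_step Spacing of output points, minutes.
#' @param times Optional explicit output times (overrides `output_step`);
#'   must start at 0 and be strictly increasing.
#' @param atol,rtol Absolute (mM) and relative solver tolerances.
#' @return A `time_course` object: a data frame with columns `time_min`,
#'   `F_mM`, `P_mM`, `I_mM`, `A_mM`, `W_mM` and provenance attributes
#'   (`config`, `rate_constants`, `solver`).
#' @export
#' @examples
#' tc <- simulate_cycle(experiment_config(F0 = 25), t_end = 40)
#' peak_anhydride(tc)
simulate_cycle <- function(config, k = default_rate_constants(), t_end = 60,
                           output_step = 0.1, times = NULL,
                           atol = 1e-9, rtol = 1e-8) {
  k <- as_rate_constants(k)
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(times)) {
    if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
    times <- seq(0, t_end, by = output_step)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  } else {
    if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
      stop("times must start at 0 and be strictly increasing", call. = FALSE)
    }
  }
  y0 <- c(F = config$F0, P = config$P0, I = 0, A = 0, W = 0)
  sol <- deSolve::ode(y0, times, cycle_rhs, k, method = "lsoda",
                      atol = atol, rtol = rtol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop(sprintf("ODE solver failed (istate = %d)", diagn[1]), call. = FALSE)
  }
  out <- as.data.frame(sol)
  names(out) <- c("time_min", "F_mM", "P_mM", "I_mM", "A_mM", "W_mM")

  pep <- out$P_mM + out$I_mM + out$A_mM
  carb <- out$F_mM + out$I_mM + out$W_mM
  pep_viol <- max(abs(pep - config$P0)) / max(config$P0, 1)
  carb_viol <- max(abs(carb - config$F0)) / max(config$F0, 1)
  if (pep_viol > 1e-6 || carb_viol > 1e-6) {
    stop(sprintf(
      "conservation violated: peptide %.3g, carbodiimide %.3g (relative)",
      pep_viol, carb_viol), call. = FALSE)
  }
  # solver round-off can leave concentrations a hair below zero
  out[-1] <- lapply(out[-1], pmax, 0)

  structure(out,
            class = c("time_course", "data.frame"),
            config = config, rate_constants = k,
            solver = list(method = "lsoda", atol = atol, rtol = rtol,
                          output_step = output_step))
}

#' Coerce a data frame to a time course
#'
#' Accepts a data frame with the serialization columns `time_min`, `F_mM`,
#' `P_mM`, `I_mM`, `A_mM`, `W_mM` (as written by [write_time_course()]) and
#' tags it as a `time_course`. No conservation check is applied: measured or
#' hand-built traces need not balance.
#'
#' @param df A data frame with the six columns above.
#' @return A `time_course` object.
#' @export
as_time_course <- function(df) {
  need <- c("time_min", "F_mM", "P_mM", "I_mM", "A_mM", "W_mM")
  if (!all(need %in% names(df))) {
    stop("data frame must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(df$time_min, strictly = TRUE)) {
    stop("time_min must be strictly increasing", call. = FALSE)
  }
  structure(as.data.frame(df)[need],
            class = c("time_course", "data.frame"))
}

#' Peak anhydride concentration
#'
#' @param tc A `time_course`.
#' @return List with `t_peak` (minutes, earliest time attaining the maximum)
#'   and `A_peak` (mM).
#' @export
peak_anhydride <- function(tc) {
  stopifnot(inherits(tc, "time_course"), nrow(tc) > 0)
  i <- which.max(tc$A_mM)
  list(t_peak = tc$time_min[i], A_peak = tc$A_mM[i])
}

# linearly interpolated time at which y crosses `level` between samples i and i+1
cross_time <- function(t, y, i, level) {
  if (y[i + 1] == y[i]) return(t[i + 1])
  t[i] + (level - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
}

#' Threshold crossing times of the anhydride trace
#'
#' Times at which the anhydride concentration first reaches a critical level
#' (`t_on`) and, after the peak, first falls back below it (`t_off`), with
#' linear interpolation between output points. Either may be `NA`: `t_on` if
#' the trace never reaches the level, `t_off` if it never falls back below.
#'
#' @param tc A `time_course`.
#' @param A_crit Critical anhydride concentration, mM (> 0). The default is
#'   the 0.9 mM critical coacervation concentration.
#' @return List with `t_on` and `t_off` in minutes (possibly `NA`).
#' @export
threshold_times <- function(tc, A_crit = 0.9) {
  stopifnot(inherits(tc, "time_course"), nrow(tc) > 0)
  if (!is.finite(A_crit) || A_crit <= 0) stop("A_crit must be > 0", call. = FALSE)
  a <- tc$A_mM; t <- tc$time_min
  on_i <- which(a >= A_crit)[1]
  if (is.na(on_i)) return(list(t_on = NA_real_, t_off = NA_real_))
  t_on <- if (on_i == 1L) t[1] else cross_time(t, a, on_i - 1L, A_crit)
  ipk <- which.max(a)
  after <- which(a < A_crit)
  after <- after[after > ipk]
  if (length(after) == 0L) return(list(t_on = t_on, t_off = NA_real_))
  j <- after[1]
  list(t_on = t_on, t_off = cross_time(t, a, j - 1L, A_crit))
}

#' Time at which fuel and product are depleted
#'
#' Earliest time after which both the fuel and the anhydride stay below a
#' detection limit (linearly interpolated). Mirrors the HPLC notion of the
#' species being "absent"; the default limit of 0.1 mM is configurable.
#'
#' @param tc A `time_course`.
#' @param detection_limit Detection limit, mM (> 0).
#' @return Depletion time in minutes; 0 if both species start below the
#'   limit; `NA` with a warning if they are not depleted within the trace.
#' @export
depletion_time <- function(tc, detection_limit = 0.1) {
  stopifnot(inherits(tc, "time_course"), nrow(tc) > 0)
  if (!is.finite(detection_limit) || detection_limit <= 0) {
    stop("detection_limit must be > 0", call. = FALSE)
  }
  v <- pmax(tc$F_mM, tc$A_mM)
  above <- which(v >= detection_limit)
  if (length(above) == 0L) return(0)
  i <- above[length(above)]
  if (i == nrow(tc)) {
    warning("fuel and product not depleted within the trace")
    return(NA_real_)
  }
  cross_time(tc$time_min, v, i, detection_limit)
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Reaction-cycle time course: %d points, 0-%g min\n",
              nrow(x), max(x$time_min)))
  cfg <- attr(x, "config")
  if (!is.null(cfg)) print(cfg)
  pk <- peak_anhydride(x)
  cat(sprintf("  peak anhydride %.3g mM at %.3g min\n", pk$A_peak, pk$t_peak))
  invisible(x)
}
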