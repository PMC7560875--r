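#' Fit reaction-cycle rate constants to HPLC time courses
#'
#' Least-squares calibration of the five rate constants against measured
#' concentrations of fuel, anhydride and/or precursor over time. Because the
#' species span orders of magnitude (tens of mM fuel, sub-mM anhydride), the
#' default loss is relative (proportional-error) least squares; absolute
#' weighting is available as a switch. Optimisation runs on the log of the
#' constants (Levenberg-Marquardt, [minpack.lm::nls.lm()]), which enforces
#' positivity without explicit bounds.
#'
#' Only unfiltered measurements are used: filtrate rows describe the outer
#' phase, not the whole mixture, and are dropped with a warning. With no
#' precursor present (`P0 = 0`) only `k0` is structurally identifiable; the
#' fit then adjusts `k0` alone, keeps the other constants at the initial
#' guess, and flags the result as under-determined.
#'
#' Data from several experiments can be fitted jointly by adding an
#' `F0_mM` (and optionally `P0_mM`) column: rows are grouped by condition
#' and a single rate-constant set is fitted across all of them. Joint
#' calibration over well-separated fuel concentrations is what makes the
#' direct-hydrolysis and activation channels separable: at high fuel the
#' precursor is drawn down substantially, which breaks the near-collinearity
#' of `k0 * F` and `k1 * F * P`.
#'
#' @param data Data frame of HPLC measurements with columns `time_min`,
#'   `species` (one of `"fuel"`, `"anhydride"`, `"precursor"`), `conc_mM`,
#'   optionally `is_filtrate` and `quench_delay_s` (see [read_hplc()]), and
#'   optionally per-row `F0_mM` / `P0_mM` for joint multi-experiment fits.
#' @param config The [experiment_config()] the data were acquired under
#'   (the default condition for rows without their own `F0_mM`/`P0_mM`).
#' @param initial_guess Starting [rate_constants()].
#' @param weighting `"relative"` (default) or `"absolute"`.
#' @param rel_floor In relative mode, residuals are scaled by
#'   `max(|obs|, rel_floor * max(|obs| of that species))` so near-zero
#'   tails do not dominate.
#' @return An object of class `cycle_fit`: the fitted [rate_constants()]
#'   (`$rate_constants`), approximate 95% confidence intervals on each
#'   constant (`$ci95`, from the Jacobian at the optimum, delta method on
#'   the log scale), the residual sum of squares (`$rss`), convergence
#'   diagnostics (`$converged`, `$message`, `$niter`), the number of
#'   observations used, and an `$under_determined` flag.
#' @export
fit_rate_constants <- function(data, config, initial_guess,
                               weighting = c("relative", "absolute"),
                               rel_floor = 0.02) {
  weighting <- match.arg(weighting)
  guess <- as_rate_constants(initial_guess)
  stopifnot(inherits(config, "experiment_config"))
  need <- c("time_min", "species", "conc_mM")
  if (!all(need %in% names(data))) {
    stop("data must have columns time_min, species, conc_mM", call. = FALSE)
  }
  if (!is.null(data$is_filtrate) && any(data$is_filtrate)) {
    warning("dropping ", sum(data$is_filtrate),
            " filtrate rows: only unfiltered data calibrate the cycle")
    data <- data[!data$is_filtrate, , drop = FALSE]
  }
  col_of <- c(fuel = "F_mM", anhydride = "A_mM", precursor = "P_mM")
  if (!all(data$species %in% names(col_of))) {
    stop("species must be fuel, anhydride or precursor", call. = FALSE)
  }

  if (is.null(data$F0_mM)) data$F0_mM <- config$F0
  if (is.null(data$P0_mM)) data$P0_mM <- config$P0

  under <- FALSE
  n_per <- table(data$species)
  if (length(n_per) < 2L || any(n_per < 4L)) {
    warning("fewer than 2 species with 4+ time points each; ",
            "fit may be under-determined")
    under <- TRUE
  }
  fuel_only <- all(data$P0_mM == 0) || all(data$species == "fuel")
  if (fuel_only) {
    warning("no precursor in the system or data: only k0 is identifiable")
    under <- TRUE
  }
  free <- if (fuel_only) "k0" else c("k0", "k1", "k2", "k3", "k4")

  obs <- data$conc_mM
  scale <- rep(1, nrow(data))
  if (weighting == "relative") {
    for (sp in unique(data$species)) {
      sel <- data$species == sp
      scale[sel] <- pmax(abs(obs[sel]), rel_floor * max(abs(obs[sel]), 1e-12))
    }
  }
  grp_key <- paste(data$F0_mM, data$P0_mM)
  groups <- lapply(unique(grp_key), function(g) {
    sel <- which(grp_key == g)
    cfg_g <- config
    cfg_g$F0 <- data$F0_mM[sel[1]]
    cfg_g$P0 <- data$P0_mM[sel[1]]
    t_out <- sort(unique(c(0, data$time_min[sel])))
    list(sel = sel, config = cfg_g, t_out = t_out,
         row_of = match(data$time_min[sel], t_out),
         col = col_of[data$species[sel]])
  })

  k_full <- unlist(guess)
  residfun <- function(lp) {
    k_full[free] <- exp(lp)
    kk <- as_rate_constants(as.list(k_full))
    pred <- tryCatch({
      p <- numeric(length(obs))
      for (g in groups) {
        tc <- simulate_cycle(g$config, kk, times = g$t_out)
        p[g$sel] <- mapply(function(r, cl) tc[[cl]][r], g$row_of, g$col)
      }
      p
    }, error = function(e) rep(Inf, length(obs)))
    if (any(!is.finite(pred))) return(rep(1e6, length(obs)))
    (pred - obs) / scale
  }
  # the direct-hydrolysis/activation split (k0 vs k1) forms a shallow
  # ridge on which Levenberg-Marquardt can stall; a small deterministic
  # multistart across that ridge makes the fit robust to the guess
  start <- log(k_full[free])
  starts <- list(start)
  if (all(c("k0", "k1") %in% free)) {
    for (shift in list(c(k0 = log(2), k1 = -log(2)),
                       c(k0 = -log(2), k1 = log(2)))) {
      s <- start
      s[names(shift)] <- s[names(shift)] + shift
      starts <- c(starts, list(s))
    }
  }
  # epsfcn keeps the finite-difference steps of the Jacobian well above the
  # ODE solver's own error, which otherwise poisons the search direction
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                     ptol = 1e-11, epsfcn = 1e-8)
  fit <- NULL
  for (s in starts) {
    f <- minpack.lm::nls.lm(s, fn = residfun, control = ctrl)
    if (is.null(fit) || f$deviance < fit$deviance) fit <- f
  }
  if (fit$info %in% c(0, 9)) {
    stop("rate-constant fit did not converge: ", fit$message, call. = FALSE)
  }
  k_full[free] <- exp(fit$par)
  k_hat <- as_rate_constants(as.list(k_full))

  # delta-method CIs on the natural scale from the log-scale covariance
  ci <- matrix(NA_real_, 5, 2,
               dimnames = list(c("k0", "k1", "k2", "k3", "k4"),
                               c("lower", "upper")))
  dof <- length(obs) - length(free)
  vc <- tryCatch({
    jtj <- fit$hessian
    s2 <- fit$deviance / max(dof, 1)
    s2 * solve(jtj)
  }, error = function(e) NULL)
  if (!is.null(vc)) {
    se_log <- sqrt(pmax(diag(vc), 0))
    ci[free, "lower"] <- exp(fit$par - 1.96 * se_log)
    ci[free, "upper"] <- exp(fit$par + 1.96 * se_log)
  }

  structure(list(
    rate_constants = k_hat,
    ci95 = as.data.frame(ci),
    rss = fit$deviance,
    converged = !(fit$info %in% c(0, 5, 9)),
    message = fit$message,
    niter = fit$niter,
    n_obs = length(obs),
    weighting = weighting,
    under_determined = under,
    free = free
  ), class = "cycle_fit")
}

#' @export
print.cycle_fit <- function(x, ...) {
  cat(sprintf("Reaction-cycle fit: %d observations, RSS %.4g (%s weighting)\n",
              x$n_obs, x$rss, x$weighting))
  if (x$under_determined) cat("  [flagged under-determined]\n")
  print(x$rate_constants)
  invisible(x)
}

#' Correct a filtrate anhydride measurement for the quench delay
#'
#' Between filtering off the droplet phase and quenching with benzylamine,
#' the filtrate still contains fuel, precursor and intermediate, so anhydride
#' keeps forming for the 15-25 s the handling takes. This correction
#' integrates the cycle model forward over the recorded delay, starting from
#' the filtrate composition, and subtracts the net anhydride produced:
#' `corrected = measured - dA(delay)`. The net production depends weakly on
#' the unknown starting anhydride, so the subtraction is iterated to
#' self-consistency (the corrected value is the starting anhydride whose
#' forward evolution over the delay reproduces the measurement); three
#' fixed-point sweeps contract the residual to negligible levels for any
#' delay up to a minute.
#'
#' @param measured_A Measured (quenched) anhydride concentration, mM.
#' @param filtrate_state Named numeric vector with the best estimate of `F`,
#'   `P` and `I` in the filtrate at filtration time (mM); an `A` element, if
#'   present, is ignored in favour of `measured_A`.
#' @param delay_s Seconds elapsed between filtration and quench (>= 0);
#'   default 20 s, the midpoint of the typical 15-25 s handling time.
#' @param k [rate_constants()].
#' @return Corrected anhydride concentration, mM, floored at zero (with a
#'   warning if the correction exceeds the measurement).
#' @export
quench_correction <- function(measured_A, filtrate_state, delay_s = 20,
                              k = default_rate_constants()) {
  k <- as_rate_constants(k)
  if (!is.finite(delay_s) || delay_s < 0) {
    stop("delay_s must be >= 0", call. = FALSE)
  }
  stopifnot(is.numeric(measured_A), length(measured_A) == 1L, measured_A >= 0)
  if (delay_s == 0) return(measured_A)
  need <- c("F", "P", "I")
  if (!all(need %in% names(filtrate_state))) {
    stop("filtrate_state must contain F, P and I", call. = FALSE)
  }
  corrected <- measured_A
  for (it in 1:3) {
    y0 <- c(F = unname(filtrate_state["F"]), P = unname(filtrate_state["P"]),
            I = unname(filtrate_state["I"]), A = max(corrected, 0), W = 0)
    sol <- deSolve::ode(y0, c(0, delay_s / 60), cycle_rhs, k,
                        method = "lsoda", atol = 1e-10, rtol = 1e-9)
    a_end <- sol[nrow(sol), "A"]
    corrected <- corrected - (a_end - measured_A)
  }
  if (corrected < 0) {
    warning("quench correction exceeds the measurement; flooring at 0")
    corrected <- 0
  }
  corrected
}

# ---- ITC ------------------------------------------------------------------

#' One-site binding model
#'
#' @param Kd Dissociation constant, mM (> 0).
#' @param dH Enthalpy per mole of bound titrant, kJ/mol.
#' @param n Stoichiometry: binding sites per cell-species molecule (here,
#'   sites per RNA monomer unit), dimensionless (> 0).
#' @return An object of class `binding_model`.
#' @export
binding_model <- function(Kd, dH, n = 1) {
  stopifnot(is.numeric(Kd), is.numeric(dH), is.numeric(n))
  if (!is.finite(Kd) || Kd <= 0 || !is.finite(n) || n <= 0) {
    stop("Kd and n must be finite and > 0", call. = FALSE)
  }
  structure(list(Kd = Kd, dH = dH, n = n), class = "binding_model")
}

#' ITC titration: geometry and (optionally) measured heats
#'
#' The default geometry mirrors the precursor-RNA titration: 26 injections
#' of 1.5 uL of 38 mM peptide into 250 uL of 1.1 mM RNA (monomer units).
#'
#' @param cell_volume_uL Working cell volume, uL.
#' @param cell_mM Cell-species concentration (RNA monomer units), mM.
#' @param syringe_mM Syringe (titrant) concentration, mM.
#' @param inj_vol_uL Per-injection volumes, uL.
#' @param heats_uJ Optional per-injection blank-subtracted heats, uJ (same
#'   length as `inj_vol_uL`).
#' @return An object of class `itc_isotherm`.
#' @export
itc_isotherm <- function(cell_volume_uL = 250, cell_mM = 1.1,
                         syringe_mM = 38, inj_vol_uL = rep(1.5, 26),
                         heats_uJ = NULL) {
  if (cell_volume_uL <= 0 || any(inj_vol_uL <= 0)) {
    stop("volumes must be > 0", call. = FALSE)
  }
  if (!is.null(heats_uJ) && length(heats_uJ) != length(inj_vol_uL)) {
    stop("heats_uJ must match inj_vol_uL in length", call. = FALSE)
  }
  structure(list(cell_volume_uL = cell_volume_uL, cell_mM = cell_mM,
                 syringe_mM = syringe_mM, inj_vol_uL = inj_vol_uL,
                 heats_uJ = heats_uJ),
            class = "itc_isotherm")
}

#' Per-injection heats of a one-site isotherm
#'
#' Forward model used both by the fit and by the synthetic generator:
#' single-site (Wiseman) binding with the standard displaced-volume
#' accounting. After a cumulative injected volume v, cell and titrant
#' concentrations are `Mt = M0 (1 - v/2V0)/(1 + v/2V0)` and
#' `Xt = X0 (v/V0)/(1 + v/2V0)`; the bound fraction comes from the one-site
#' quadratic, and the heat of injection i is the difference in cell heat
#' content plus the heat carried out in the displaced volume.
#'
#' @param model A [binding_model()].
#' @param design An [itc_isotherm()] (heats, if present, are ignored).
#' @return Numeric vector of per-injection heats, uJ.
#' @export
wiseman_heats <- function(model, design) {
  stopifnot(inherits(model, "binding_model"), inherits(design, "itc_isotherm"))
  V0 <- design$cell_volume_uL
  v <- cumsum(design$inj_vol_uL)
  Mt <- design$cell_mM * (1 - v / (2 * V0)) / (1 + v / (2 * V0))
  Xt <- design$syringe_mM * (v / V0) / (1 + v / (2 * V0))
  r <- Xt / (model$n * Mt)
  s <- model$Kd / (model$n * Mt)
  theta <- 0.5 * (1 + r + s - sqrt((1 + r + s)^2 - 4 * r))
  # mM * uL * kJ/mol = nmol * uJ/nmol = uJ
  Q <- model$n * Mt * model$dH * V0 * theta
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (design$inj_vol_uL / V0) * (Q + Qprev) / 2
}

#' Fit the one-site binding model to an ITC isotherm
#'
#' Least-squares fit of `n`, `Kd` and `dH` of the one-site (Wiseman)
#' isotherm, with per-injection dilution and displaced-volume accounting,
#' to blank-subtracted heats. The first injection is excluded by default
#' (the usual partial-delivery artefact). `n` and `Kd` are fitted on the
#' log scale to keep them positive.
#'
#' At low c-value (`c = n * cell_mM / Kd` below ~1) the parameters are
#' strongly correlated; the fit then still returns point estimates but
#' flags `low_c = TRUE` and reports wide confidence intervals rather than
#' failing. An all-zero isotherm is flagged unidentifiable.
#'
#' @param isotherm An [itc_isotherm()] with `heats_uJ` present.
#' @param skip_first Exclude the first injection from the fit (default TRUE).
#' @param start Optional [binding_model()] used as the starting point.
#' @return Object of class `binding_fit`: `$model` (a [binding_model()]),
#'   `$ci95`, `$rss`, `$converged`, `$low_c`, `$unidentifiable`.
#' @export
fit_binding_isotherm <- function(isotherm, skip_first = TRUE, start = NULL) {
  stopifnot(inherits(isotherm, "itc_isotherm"))
  q <- isotherm$heats_uJ
  if (is.null(q)) stop("isotherm carries no heats to fit", call. = FALSE)
  if (length(q) < 10L) stop("need at least 10 injections", call. = FALSE)

  if (all(abs(q) < 1e-9)) {
    return(structure(list(
      model = NULL, ci95 = NULL, rss = 0, converged = FALSE,
      low_c = NA, unidentifiable = TRUE), class = "binding_fit"))
  }
  idx <- if (skip_first) seq_along(q)[-1] else seq_along(q)
  if (is.null(start)) {
    dh0 <- sum(q) / (isotherm$cell_mM * isotherm$cell_volume_uL)
    start <- binding_model(Kd = isotherm$cell_mM, dH = dh0, n = 1)
  }
  residfun <- function(p) {
    m <- binding_model(Kd = exp(p[2]), dH = p[3], n = exp(p[1]))
    (wiseman_heats(m, isotherm) - q)[idx]
  }
  p0 <- c(log(start$n), log(start$Kd), start$dH)
  fit <- minpack.lm::nls.lm(p0, fn = residfun,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  m_hat <- binding_model(Kd = exp(fit$par[2]), dH = fit$par[3],
                         n = exp(fit$par[1]))
  cval <- m_hat$n * isotherm$cell_mM / m_hat$Kd

  ci <- matrix(NA_real_, 3, 2,
               dimnames = list(c("n", "Kd", "dH"), c("lower", "upper")))
  vc <- tryCatch({
    s2 <- fit$deviance / max(length(idx) - 3, 1)
    s2 * solve(fit$hessian)
  }, error = function(e) NULL)
  if (!is.null(vc)) {
    se <- sqrt(pmax(diag(vc), 0))
    ci["n", ] <- exp(fit$par[1] + c(-1.96, 1.96) * se[1])
    ci["Kd", ] <- exp(fit$par[2] + c(-1.96, 1.96) * se[2])
    ci["dH", ] <- fit$par[3] + c(-1.96, 1.96) * se[3]
  }

  structure(list(
    model = m_hat, ci95 = as.data.frame(ci), rss = fit$deviance,
    converged = !(fit$info %in% c(0, 5, 9)),
    c_value = cval, low_c = cval < 1, unidentifiable = FALSE
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$unidentifiable) {
    cat("ITC fit: unidentifiable (all heats zero)\n")
    return(invisible(x))
  }
  cat(sprintf("One-site ITC fit: Kd = %.3g mM, dH = %.3g kJ/mol, n = %.3g (c = %.2g%s)\n",
              x$model$Kd, x$model$dH, x$model$n, x$c_value,
              if (isTRUE(x$low_c)) ", low c: wide intervals" else ""))
  invisible(x)
}
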