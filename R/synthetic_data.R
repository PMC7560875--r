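#' Noise specification for the synthetic-data generators
#'
#' @param relative Relative (multiplicative) noise fraction.
#' @param floor Additive noise floor, in the units of the generated signal.
#' @param seed Integer random seed; recorded in every generated output so
#'   each generator is a pure function of (truth, design, seed).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(relative = 0, floor = 0, seed = 1L) {
  stopifnot(relative >= 0, floor >= 0, is.finite(seed))
  structure(list(relative = relative, floor = floor, seed = as.integer(seed)),
            class = "noise_spec")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic HPLC time-course measurements
#'
#' Samples the reaction-cycle model at the requested times and perturbs the
#' concentrations with multiplicative Gaussian noise plus an additive floor
#' (instrument-proportional error). When `filtrate = TRUE`, the anhydride
#' values are the model advanced by the quench delay, emulating the product
#' formed in the filtrate between filtration and benzylamine quench, so
#' that [quench_correction()] can be round-trip tested against the
#' generator.
#'
#' @param config [experiment_config()].
#' @param k [rate_constants()].
#' @param sample_times Sampling times, minutes (> 0).
#' @param noise [noise_spec()].
#' @param species Which species are measured.
#' @param filtrate Emulate filtrate samples?
#' @param quench_delay_s Delay between filtration and quench, seconds.
#' @return Data frame in the HPLC schema (`time_min`, `species`, `conc_mM`,
#'   `is_filtrate`, `quench_delay_s`), with the seed and the noiseless
#'   values attached as attributes `seed` and `truth`.
#' @export
synth_hplc <- function(config, k = default_rate_constants(), sample_times,
                       noise = noise_spec(),
                       species = c("fuel", "anhydride"),
                       filtrate = FALSE, quench_delay_s = 20) {
  stopifnot(all(sample_times > 0))
  species <- match.arg(species, c("fuel", "anhydride", "precursor"),
                       several.ok = TRUE)
  delay_min <- quench_delay_s / 60
  t_all <- sort(unique(c(0, sample_times, if (filtrate) sample_times + delay_min)))
  tc <- simulate_cycle(config, k, times = t_all)
  col_of <- c(fuel = "F_mM", anhydride = "A_mM", precursor = "P_mM")

  rows <- do.call(rbind, lapply(species, function(sp) {
    tq <- if (filtrate && sp == "anhydride") sample_times + delay_min else sample_times
    vals <- tc[[col_of[sp]]][match(tq, tc$time_min)]
    data.frame(time_min = sample_times, species = sp, conc_mM = vals,
               is_filtrate = filtrate,
               quench_delay_s = if (filtrate) quench_delay_s else NA_real_)
  }))
  truth <- rows$conc_mM
  rows$conc_mM <- with_seed(noise$seed, {
    pmax(truth * (1 + noise$relative * stats::rnorm(length(truth))) +
           noise$floor * stats::rnorm(length(truth)), 0)
  })
  attr(rows, "seed") <- noise$seed
  attr(rows, "truth") <- truth
  rows
}

#' Turbidity response model
#'
#' Maps anhydride concentration to blank-subtracted absorbance at 600 nm.
#' In the dynamic regime the absorbance tracks the product above the
#' coacervation threshold (`scale * max(0, A - A_crit)`). In the metastable
#' regime droplets are kinetically arrested: after its maximum the
#' absorbance holds (hysteresis) until the persistence time, then collapses.
#'
#' @param scale Absorbance per mM of anhydride above the threshold, a.u./mM.
#' @param A_crit Critical coacervation concentration, mM.
#' @param persistence_min For the metastable regime: minutes after fuel
#'   addition that the turbidity persists (default 76).
#' @param regime `"dynamic"` or `"metastable"`.
#' @return Object of class `turbidity_model`.
#' @export
turbidity_model <- function(scale = 0.25, A_crit = 0.9, persistence_min = 76,
                            regime = c("dynamic", "metastable")) {
  stopifnot(scale > 0, persistence_min >= 0)
  structure(list(scale = scale, A_crit = A_crit,
                 persistence_min = persistence_min,
                 regime = match.arg(regime)),
            class = "turbidity_model")
}

#' Synthetic plate-reader turbidity trace
#'
#' @param tc A `time_course` covering the requested times.
#' @param model A [turbidity_model()].
#' @param noise [noise_spec()]; additive Gaussian with sd `floor`.
#' @param times Sampling times, minutes (default: every minute over the
#'   course, the plate-reader cadence).
#' @return A [turbidity_trace()] with attributes `seed` and `truth`.
#' @export
synth_turbidity <- function(tc, model = turbidity_model(),
                            noise = noise_spec(), times = NULL) {
  stopifnot(inherits(tc, "time_course"), inherits(model, "turbidity_model"))
  if (is.null(times)) times <- seq(0, floor(max(tc$time_min)), by = 1)
  if (max(times) > max(tc$time_min)) {
    stop("time course does not cover the requested times", call. = FALSE)
  }
  a <- stats::approx(tc$time_min, tc$A_mM, xout = times)$y
  base <- model$scale * pmax(0, a - model$A_crit)
  vals <- base
  if (model$regime == "metastable" && any(base > 0)) {
    ipk <- which.max(base)
    vals[seq_along(vals) > ipk] <- base[ipk]
    vals[times >= model$persistence_min] <- 0
  }
  truth <- vals
  vals <- with_seed(noise$seed,
                    truth + noise$floor * stats::rnorm(length(truth)))
  tr <- turbidity_trace(times, vals)
  attr(tr, "seed") <- noise$seed
  attr(tr, "truth") <- truth
  tr
}

#' Synthetic ITC isotherm
#'
#' Per-injection heats from the one-site forward model
#' ([wiseman_heats()]) with multiplicative Gaussian noise.
#'
#' @param truth A [binding_model()]: the ground-truth affinity.
#' @param design An [itc_isotherm()] giving the titration geometry; the
#'   default mirrors the precursor-RNA experiment (26 injections of
#'   1.5 uL).
#' @param noise [noise_spec()].
#' @return The `design` isotherm with `heats_uJ` filled in, plus `seed` and
#'   `truth` attributes.
#' @export
synth_itc <- function(truth = binding_model(Kd = 2.9, dH = -4, n = 1),
                      design = itc_isotherm(), noise = noise_spec()) {
  q0 <- wiseman_heats(truth, design)
  q <- with_seed(noise$seed, {
    q0 * (1 + noise$relative * stats::rnorm(length(q0))) +
      noise$floor * stats::rnorm(length(q0))
  })
  design$heats_uJ <- q
  attr(design, "seed") <- noise$seed
  attr(design, "truth") <- truth
  design
}

#' Synthetic fluorescence micrograph with ground truth
#'
#' Draws non-overlapping disk-shaped droplets on a uniform background,
#' applies a Gaussian point-spread blur, then signal-dependent
#' Poisson-Gaussian noise (shot noise plus read noise). Droplet interiors
#' are `K_true` times the background intensity, so the frame carries a
#' known partition coefficient. The ground-truth droplet table is returned
#' alongside the frame; nothing about the truth is hidden in state.
#'
#' @param n_droplets Number of droplets to place.
#' @param frame_size Frame side length, pixels.
#' @param pixel_size_um Pixel size, um/px.
#' @param radius_range_px Range of droplet radii, px.
#' @param background Mean background intensity, counts. Shot noise makes
#'   the background SNR `sqrt(background)`.
#' @param K_true True interior/background intensity ratio.
#' @param psf_sigma_px Gaussian PSF sigma, px.
#' @param read_noise_sd Additive Gaussian read noise sd, counts.
#' @param time_min Acquisition time stamp carried on the frame.
#' @param seed Random seed.
#' @return List with `frame` (a [micrograph_frame()]) and `truth` (data
#'   frame `row`, `col`, `radius_px` per droplet).
#' @export
synth_micrograph <- function(n_droplets = 25, frame_size = 512,
                             pixel_size_um = 0.25,
                             radius_range_px = c(6, 14),
                             background = 30, K_true = 37,
                             psf_sigma_px = 2, read_noise_sd = 2,
                             time_min = NA_real_, seed = 1L) {
  stopifnot(n_droplets >= 0, frame_size > 0, background > 0, K_true > 0)
  res <- with_seed(seed, {
    rr <- cc <- rad <- numeric(0)
    tries <- 0L
    while (length(rad) < n_droplets && tries < 20000L) {
      tries <- tries + 1L
      ri <- stats::runif(1, radius_range_px[1], radius_range_px[2])
      margin <- ri + 3 * psf_sigma_px
      xi <- stats::runif(1, margin, frame_size - margin)
      yi <- stats::runif(1, margin, frame_size - margin)
      if (all(sqrt((rr - xi)^2 + (cc - yi)^2) >
                (rad + ri + 4 * psf_sigma_px))) {
        rr <- c(rr, xi); cc <- c(cc, yi); rad <- c(rad, ri)
      }
    }
    if (length(rad) < n_droplets) {
      stop("could not place ", n_droplets, " non-overlapping droplets",
           call. = FALSE)
    }
    rg <- matrix(rep(seq_len(frame_size), frame_size), frame_size)
    cg <- t(rg)
    img <- matrix(background, frame_size, frame_size)
    for (i in seq_along(rad)) {
      img[(rg - rr[i])^2 + (cg - cc[i])^2 <= rad[i]^2] <- background * K_true
    }
    if (psf_sigma_px > 0) {
      mx <- max(img)
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img / mx),
                                               sigma = psf_sigma_px)) * mx
    }
    noisy <- matrix(stats::rpois(frame_size^2, pmax(as.numeric(img), 0)),
                    frame_size) +
      matrix(stats::rnorm(frame_size^2, 0, read_noise_sd), frame_size)
    list(img = pmax(noisy, 0),
         truth = data.frame(row = rr, col = cc, radius_px = rad))
  })
  list(frame = micrograph_frame(res$img, pixel_size_um = pixel_size_um,
                                time_min = time_min),
       truth = res$truth)
}

#' Synthetic micrograph time-lapse driven by a reaction-cycle course
#'
#' Frames whose droplet count scales with the instantaneous anhydride
#' excess over the coacervation threshold,
#' `n(t) = round(count_scale * max(0, A(t) - A_crit))`. This coupling is a
#' deliberately simple stand-in that exists to exercise the imaging
#' estimators against known ground truth; it is not a physical model of
#' nucleation.
#'
#' @param tc A `time_course`.
#' @param times Frame acquisition times, minutes.
#' @param count_scale Droplets per mM of anhydride above threshold.
#' @param A_crit Coacervation threshold, mM.
#' @param seed Base seed; frame i uses `seed + i`.
#' @param ... Passed to [synth_micrograph()] (sizes, noise, `K_true`, ...).
#' @return List of per-frame lists with components `frame` and `truth`.
#' @export
synth_timelapse <- function(tc, times = seq(1, 25, by = 1), count_scale = 8,
                            A_crit = 0.9, seed = 1L, ...) {
  stopifnot(inherits(tc, "time_course"))
  a <- stats::approx(tc$time_min, tc$A_mM, xout = times)$y
  lapply(seq_along(times), function(i) {
    n <- round(count_scale * max(0, a[i] - A_crit))
    synth_micrograph(n_droplets = n, time_min = times[i],
                     seed = seed + i, ...)
  })
}
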