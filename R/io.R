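#' Write a reaction-cycle time course to CSV
#'
#' Writes the standard schema `time_min,F_mM,P_mM,I_mM,A_mM,W_mM` plus a
#' JSON provenance sidecar (`<path>.json`) recording the experiment
#' configuration, rate constants, solver settings and package version.
#'
#' @param tc A `time_course`.
#' @param path Output CSV path.
#' @param sidecar Write the provenance sidecar?
#' @return `path`, invisibly.
#' @export
write_time_course <- function(tc, path, sidecar = TRUE) {
  stopifnot(inherits(tc, "time_course"))
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  if (sidecar) {
    cfg <- attr(tc, "config")
    prov <- list(
      config = if (is.null(cfg)) NULL else unclass(cfg),
      rate_constants = unclass(attr(tc, "rate_constants")),
      solver = attr(tc, "solver"),
      package_version = as.character(utils::packageVersion("fueldrops"))
    )
    jsonlite::write_json(prov, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a time course written by [write_time_course()]
#' @param path CSV path.
#' @return A `time_course` (no conservation check is applied on read).
#' @export
read_time_course <- function(path) {
  as_time_course(utils::read.csv(path))
}

#' Read/write HPLC measurement tables
#'
#' Schema: `time_min,species,conc_mM,is_filtrate,quench_delay_s`, with
#' `quench_delay_s` present (non-NA) only on filtrate rows.
#'
#' @param path CSV path.
#' @return `read_hplc`: a validated data frame in the schema above.
#' @export
read_hplc <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_min", "species", "conc_mM")
  if (!all(need %in% names(d))) {
    stop("HPLC file must have columns time_min, species, conc_mM", call. = FALSE)
  }
  if (is.null(d$is_filtrate)) d$is_filtrate <- FALSE
  if (is.null(d$quench_delay_s)) d$quench_delay_s <- NA_real_
  if (any(d$conc_mM < 0, na.rm = TRUE)) {
    stop("negative concentration in HPLC file", call. = FALSE)
  }
  if (any(!d$is_filtrate & !is.na(d$quench_delay_s))) {
    stop("quench_delay_s must be absent on unfiltered rows", call. = FALSE)
  }
  d
}

#' @rdname read_hplc
#' @param data HPLC data frame in the schema above.
#' @export
write_hplc <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read/write turbidity traces (`time_min,abs600`)
#' @param path CSV path.
#' @export
read_turbidity <- function(path) {
  d <- utils::read.csv(path)
  turbidity_trace(d$time_min, d$abs600)
}

#' @rdname read_turbidity
#' @param trace A [turbidity_trace()].
#' @export
write_turbidity <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read/write ITC isotherms
#'
#' The CSV holds the per-injection table (`inj_vol_uL,heat_uJ`); the cell
#' and syringe concentrations travel in a JSON header sidecar
#' (`<path>.json`).
#'
#' @param path CSV path (the sidecar is `<path>.json`).
#' @export
read_itc <- function(path) {
  d <- utils::read.csv(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  itc_isotherm(cell_volume_uL = hdr$cell_volume_uL, cell_mM = hdr$cell_mM,
               syringe_mM = hdr$syringe_mM, inj_vol_uL = d$inj_vol_uL,
               heats_uJ = d$heat_uJ)
}

#' @rdname read_itc
#' @param isotherm An [itc_isotherm()] with heats present.
#' @export
write_itc <- function(isotherm, path) {
  stopifnot(inherits(isotherm, "itc_isotherm"))
  utils::write.csv(
    data.frame(inj_vol_uL = isotherm$inj_vol_uL,
               heat_uJ = if (is.null(isotherm$heats_uJ)) NA_real_
                         else isotherm$heats_uJ),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(cell_volume_uL = isotherm$cell_volume_uL,
         cell_mM = isotherm$cell_mM, syringe_mM = isotherm$syringe_mM),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
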