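#' A single fluorescence micrograph frame
#'
#' @param pixels Numeric matrix of non-negative pixel intensities (a.u.).
#' @param pixel_size_um Pixel size, micrometres per pixel (> 0).
#' @param time_min Acquisition time since fuel addition, minutes.
#' @param channel Channel label, e.g. an emission band.
#' @return Object of class `micrograph_frame`.
#' @export
micrograph_frame <- function(pixels, pixel_size_um = 1, time_min = NA_real_,
                             channel = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 time_min = time_min, channel = channel),
            class = "micrograph_frame")
}

#' @export
print.micrograph_frame <- function(x, ...) {
  cat(sprintf("Micrograph %dx%d px (%.3g um/px), t = %s min, channel %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              format(x$time_min), format(x$channel)))
  invisible(x)
}

#' Segment droplets in a micrograph
#'
#' Thresholds the frame (Otsu by default, or a fixed intensity), labels
#' connected components, discards components smaller than `min_area_px`,
#' and measures each droplet. Volumes assume perfectly spherical droplets:
#' the equivalent diameter comes from the 2-D area
#' (`d = 2 sqrt(area / pi)`) and `volume = pi/6 d^3`.
#'
#' Touching droplets are not split: fusion makes merged objects physically
#' real here. A droplet containing an interior dark region (a vacuole) is
#' counted once; set `annotate_vacuoles = TRUE` to flag droplets whose
#' filled outline contains interior holes.
#'
#' @param frame A [micrograph_frame()].
#' @param threshold_method `"otsu"` (on the intensity-normalised frame) or
#'   `"fixed"`.
#' @param threshold_value Intensity threshold in the frame's units, used
#'   when `threshold_method = "fixed"`.
#' @param min_area_px Minimum component area in pixels (components below
#'   this are discarded).
#' @param annotate_vacuoles Add a logical `has_vacuole` column.
#' @return Data frame with one row per droplet: `label`, `centroid_row`,
#'   `centroid_col` (px), `area_px`, `eq_diam_um`, `volume_um3`,
#'   `mean_intensity`, and optionally `has_vacuole`. A blank frame yields
#'   zero rows. The retained binary mask and the threshold used are
#'   attached as attributes `mask` and `threshold`.
#' @export
segment_droplets <- function(frame, threshold_method = c("otsu", "fixed"),
                             threshold_value = NULL, min_area_px = 4,
                             annotate_vacuoles = FALSE) {
  stopifnot(inherits(frame, "micrograph_frame"))
  threshold_method <- match.arg(threshold_method)
  img <- frame$pixels
  empty <- data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = numeric(0),
                      eq_diam_um = numeric(0), volume_um3 = numeric(0),
                      mean_intensity = numeric(0))
  if (annotate_vacuoles) empty$has_vacuole <- logical(0)

  if (threshold_method == "otsu") {
    rng <- range(img)
    if (rng[2] <= rng[1]) {  # uniform frame: nothing to segment
      attr(empty, "mask") <- matrix(FALSE, nrow(img), ncol(img))
      attr(empty, "threshold") <- NA_real_
      return(empty)
    }
    norm <- (img - rng[1]) / (rng[2] - rng[1])
    th_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    th <- rng[1] + th_norm * (rng[2] - rng[1])
  } else {
    if (is.null(threshold_value)) {
      stop("threshold_value required for fixed thresholding", call. = FALSE)
    }
    th <- threshold_value
  }
  mask <- img > th
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))

  if (max(lab) == 0) {
    attr(empty, "mask") <- mask & FALSE
    attr(empty, "threshold") <- th
    return(empty)
  }
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0) {
    attr(empty, "mask") <- mask & FALSE
    attr(empty, "threshold") <- th
    return(empty)
  }
  lab[!(lab %in% keep)] <- 0L
  mask <- lab > 0

  idx <- which(lab > 0)
  lv <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  c_row <- tapply(rows, lv, mean)
  c_col <- tapply(cols, lv, mean)
  m_int <- tapply(img[idx], lv, mean)
  area <- as.numeric(areas[keep])
  d_um <- 2 * sqrt(area / pi) * frame$pixel_size_um

  out <- data.frame(
    label = keep,
    centroid_row = as.numeric(c_row),
    centroid_col = as.numeric(c_col),
    area_px = area,
    eq_diam_um = d_um,
    volume_um3 = pi / 6 * d_um^3,
    mean_intensity = as.numeric(m_int)
  )
  if (annotate_vacuoles) {
    filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0
    holes <- filled & !mask
    # a hole belongs to the droplet whose filled outline contains it
    lab_fill <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(filled)))
    hole_labs <- unique(lab_fill[holes])
    out$has_vacuole <- vapply(out$label, function(l) {
      fl <- lab_fill[lab == l][1]
      fl %in% hole_labs
    }, logical(1))
  }
  attr(out, "mask") <- mask
  attr(out, "threshold") <- th
  out
}

#' Time-binned droplet statistics over a micrograph time-lapse
#'
#' Aggregates per-droplet measurements into contiguous time bins (default
#' width 5 min, matching the convention that one data point summarises five
#' 1-min frames). Droplet counts are averaged per frame within a bin;
#' volumes and intensities are pooled over all droplets in the bin. Bins
#' with no frames are absent from the output, not zero.
#'
#' @param frames A list whose elements are lists with components `frame`
#'   (a [micrograph_frame()] carrying `time_min`) and `records` (its
#'   [segment_droplets()] output).
#' @param bin_width Bin width in minutes.
#' @return Data frame with one row per non-empty bin: `bin_start`,
#'   `bin_end`, `bin_mid`, `n_frames`, `count_mean`, `count_sd`,
#'   `volume_mean_um3`, `volume_sd_um3`, `intensity_mean`, `intensity_sd`,
#'   `n_droplets`.
#' @export
timelapse_stats <- function(frames, bin_width = 5) {
  stopifnot(length(frames) > 0, bin_width > 0)
  tms <- vapply(frames, function(f) f$frame$time_min, numeric(1))
  if (any(!is.finite(tms))) stop("all frames must be time-stamped", call. = FALSE)
  counts <- vapply(frames, function(f) nrow(f$records), numeric(1))
  breaks <- seq(0, ceiling(max(tms) / bin_width) * bin_width, by = bin_width)
  bin <- cut(tms, breaks, include.lowest = TRUE, right = TRUE)

  per_droplet <- do.call(rbind, lapply(seq_along(frames), function(i) {
    r <- frames[[i]]$records
    if (nrow(r) == 0) return(NULL)
    data.frame(bin = bin[i], volume = r$volume_um3, intensity = r$mean_intensity)
  }))

  res <- lapply(levels(bin), function(b) {
    sel <- which(bin == b)
    if (length(sel) == 0) return(NULL)
    lo <- breaks[match(b, levels(bin))]
    dr <- if (is.null(per_droplet)) NULL else per_droplet[per_droplet$bin == b, ]
    data.frame(
      bin_start = lo, bin_end = lo + bin_width, bin_mid = lo + bin_width / 2,
      n_frames = length(sel),
      count_mean = mean(counts[sel]),
      count_sd = stats::sd(counts[sel]),
      volume_mean_um3 = if (is.null(dr) || nrow(dr) == 0) NA_real_ else mean(dr$volume),
      volume_sd_um3 = if (is.null(dr) || nrow(dr) == 0) NA_real_ else stats::sd(dr$volume),
      intensity_mean = if (is.null(dr) || nrow(dr) == 0) NA_real_ else mean(dr$intensity),
      intensity_sd = if (is.null(dr) || nrow(dr) == 0) NA_real_ else stats::sd(dr$intensity),
      n_droplets = if (is.null(dr)) 0L else nrow(dr)
    )
  })
  do.call(rbind, res)
}

#' Partition coefficient from a segmented micrograph
#'
#' Estimates the partition coefficient K of the imaged solute as the ratio
#' of the median intensity inside droplets to the median intensity outside.
#' To avoid the blurred rim biasing either side, the interior is the droplet
#' mask eroded by 2 px and the background is the complement of the mask
#' dilated by 2 px; medians make both robust to noise.
#'
#' @param frame A [micrograph_frame()].
#' @param records The [segment_droplets()] output for that frame (its
#'   `mask` attribute is used).
#' @return Object of class `partition_estimate`: `K`, `interior_median`,
#'   `background_median`, `n_droplets`, `unbounded` (TRUE with a warning
#'   when the background median is zero).
#' @export
partition_coefficient <- function(frame, records) {
  stopifnot(inherits(frame, "micrograph_frame"))
  if (nrow(records) < 1) {
    stop("need at least one segmented droplet", call. = FALSE)
  }
  mask <- attr(records, "mask")
  if (is.null(mask)) stop("records carry no mask attribute", call. = FALSE)
  brush <- EBImage::makeBrush(5, "disc")  # radius-2 structuring element
  interior <- EBImage::imageData(EBImage::erode(EBImage::Image(mask), brush)) > 0
  background <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask), brush)) == 0
  if (!any(interior)) interior <- mask  # tiny droplets: fall back to the mask
  if (!any(background)) {
    stop("no background pixels outside the dilated droplet mask", call. = FALSE)
  }
  img <- frame$pixels
  med_in <- stats::median(img[interior])
  med_bg <- stats::median(img[background])
  unbounded <- med_bg <= 0
  if (unbounded) warning("zero background median: partition estimate unbounded")
  structure(list(
    K = if (unbounded) Inf else med_in / med_bg,
    interior_median = med_in, background_median = med_bg,
    n_droplets = nrow(records), unbounded = unbounded
  ), class = "partition_estimate")
}

#' @export
print.partition_estimate <- function(x, ...) {
  cat(sprintf("Partition coefficient K = %.3g (interior %.3g / background %.3g, %d droplets)\n",
              x$K, x$interior_median, x$background_median, x$n_droplets))
  invisible(x)
}
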