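# Scanned-film handling: load 16-bit scans, red-channel ROI statistics,
# pixelwise conversion to dose maps.

new_film_scan <- function(pixels, dpi, channels, scan_delay_h = 24,
                          film_model = NA_character_) {
  stopifnot(is.matrix(pixels), dpi > 0)
  structure(
    list(
      pixels = pixels, # red channel, 16-bit scale
      dpi = dpi,
      mm_per_pixel = 25.4 / dpi,
      channels = channels,
      scan_delay_h = scan_delay_h,
      film_model = film_model
    ),
    class = "film_scan"
  )
}

#' @export
print.film_scan <- function(x, ...) {
  cat(sprintf("<film_scan> %d x %d px, %g dpi (%.4f mm/px), %s\n",
              nrow(x$pixels), ncol(x$pixels), x$dpi, x$mm_per_pixel,
              x$channels))
  invisible(x)
}

#' Load a scanned film image
#'
#' Reads an 8- or 16-bit grayscale or RGB TIFF/PNG film scan. The red
#' channel is retained for dosimetry (radiochromic film is analysed on the
#' red channel); 8-bit inputs are rescaled to the 16-bit scale (x257) with a
#' warning. Scan resolution is taken from the TIFF metadata, from a JSON
#' sidecar (`<path>.json` with a `dpi` field, as written by [render_film()]),
#' or from `dpi_override`; with none of these the call errors, because the
#' mm-per-pixel scale would be undefined.
#'
#' @param path Path to a TIFF or PNG file.
#' @param dpi_override Optional scan resolution in dots per inch, used when
#'   the file carries no resolution metadata.
#' @param scan_delay_h Hours between exposure and scan (metadata only;
#'   default 24, the standard darkening delay).
#' @return A `film_scan` object with elements `pixels` (red channel, 16-bit
#'   scale), `dpi`, `mm_per_pixel` (= 25.4 / dpi), `channels`,
#'   `scan_delay_h` and `film_model` (from the sidecar when present).
#' @export
load_scan <- function(path, dpi_override = NULL, scan_delay_h = 24) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  dpi <- NULL
  film_model <- NA_character_

  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
    bits <- attr(img, "bits.per.sample") %||% 16L
    xres <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit") %||% "inch"
    if (!is.null(xres) && identical(unit, "inch")) dpi <- xres
  } else if (ext == "png") {
    # readPNG returns [0,1] regardless of stored depth; 8-bit values land on
    # the 16-bit scale via the same x257 step (255/255 * 65535)
    img <- round(png::readPNG(path) * 65535)
    bits <- 16L
  } else {
    stopf("unsupported image format: .%s (use TIFF or PNG)", ext)
  }

  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    dpi <- dpi %||% meta$dpi
    film_model <- meta$film_model %||% NA_character_
  }
  dpi <- dpi_override %||% dpi
  if (is.null(dpi)) {
    stopf("no scan resolution: file has no dpi metadata and no dpi_override was given")
  }

  channels <- if (length(dim(img)) == 3L) "RGB" else "red-only"
  red <- if (channels == "RGB") img[, , 1L] else img
  red <- matrix(as.numeric(red), nrow = nrow(red))

  if (ext %in% c("tif", "tiff") && bits == 8L) {
    warnf("8-bit input rescaled to the 16-bit scale (x257)")
    red <- red * 257
  }
  if (any(red < 0 | red > 65535)) stopf("pixel values outside the 16-bit scale")

  new_film_scan(red, dpi = dpi, channels = channels,
                scan_delay_h = scan_delay_h, film_model = film_model)
}

#' Mean pixel value in a square region of interest
#'
#' Arithmetic mean of the red-channel values inside a square ROI, the
#' standard film readout (default 50 x 50 pixels at the centre of the
#' exposed region).
#'
#' @param scan A `film_scan`.
#' @param center Integer `(row, col)` of the ROI centre, 1-based; defaults
#'   to the image centre.
#' @param size Side length in pixels (default 50).
#' @return The mean pixel value (scalar).
#' @export
roi_mean_pixel <- function(scan, center = NULL, size = 50L) {
  stopifnot(inherits(scan, "film_scan"))
  dims <- dim(scan$pixels)
  center <- center %||% round(dims / 2)
  half_lo <- floor((size - 1) / 2)
  half_hi <- ceiling((size - 1) / 2)
  rows <- (center[1] - half_lo):(center[1] + half_hi)
  cols <- (center[2] - half_lo):(center[2] + half_hi)
  if (min(rows) < 1L || min(cols) < 1L || max(rows) > dims[1] || max(cols) > dims[2]) {
    stopf("ROI (%d x %d at %d,%d) extends outside the %d x %d image",
          size, size, center[1], center[2], dims[1], dims[2])
  }
  mean(scan$pixels[rows, cols])
}

#' Convert a film scan to a dose map
#'
#' Applies [dose_from_pixel()] pixelwise. Pixels outside the calibrated
#' pixel span (plus guard band) are masked (`NA`), never clipped, so that
#' statistics over shielded regions are not silently biased; for the same
#' reason, in-span per-pixel doses are not clipped at the 0 Gy floor --
#' grain noise around an unexposed level converts to small symmetric
#' positive and negative doses that average out over a region. A film-model
#' mismatch between scan metadata and curve warns but proceeds.
#'
#' @param scan A `film_scan`.
#' @param curve An `hd_curve`.
#' @return A `dose_map` object: `dose` (matrix, Gy, `NA` where masked),
#'   `mm_per_pixel`, `film_model`, `n_masked`.
#' @export
dose_map <- function(scan, curve) {
  stopifnot(inherits(scan, "film_scan"), inherits(curve, "hd_curve"))
  if (!is.na(scan$film_model) && !identical(scan$film_model, curve$film_model)) {
    warnf("film model mismatch: scan is %s but curve was built for %s",
          scan$film_model, curve$film_model)
  }
  dose <- dose_from_pixel_masked(curve, as.numeric(scan$pixels))
  dose <- matrix(dose, nrow = nrow(scan$pixels))
  structure(
    list(
      dose = dose,
      mm_per_pixel = scan$mm_per_pixel,
      film_model = curve$film_model,
      n_masked = sum(is.na(dose))
    ),
    class = "dose_map"
  )
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d px (%.4f mm/px), %d masked\n",
              nrow(x$dose), ncol(x$dose), x$mm_per_pixel, x$n_masked))
  rng <- range(x$dose, na.rm = TRUE)
  cat(sprintf("  dose range: %.3g-%.3g Gy\n", rng[1], rng[2]))
  invisible(x)
}

#' Extract a 1-D dose profile from a dose map
#'
#' Takes a single row or column of the dose map (optionally averaged over a
#' band of neighbouring lines to suppress grain) and returns it as a profile
#' tibble in mm. Positions are measured from the image centre.
#'
#' @param dm A `dose_map`.
#' @param axis `"row"` (profile runs along a row, left-right) or `"col"`.
#' @param index Row/column index; defaults to the central line.
#' @param band Half-width in lines over which to average (default 2, i.e. 5
#'   lines).
#' @param margin_mm Optional tumour-margin position on the profile axis,
#'   attached as the `margin_mm` attribute.
#' @return A tibble with `position_mm` and `dose_gy`, masked pixels dropped.
#' @export
profile_from_dose_map <- function(dm, axis = c("row", "col"), index = NULL,
                                  band = 2L, margin_mm = NULL) {
  stopifnot(inherits(dm, "dose_map"))
  axis <- match.arg(axis)
  dims <- dim(dm$dose)
  if (axis == "row") {
    index <- index %||% round(dims[1] / 2)
    lines <- dm$dose[pmax(1, index - band):pmin(dims[1], index + band), ,
                     drop = FALSE]
    dose <- colMeans(lines, na.rm = TRUE)
    n <- dims[2]
  } else {
    index <- index %||% round(dims[2] / 2)
    lines <- dm$dose[, pmax(1, index - band):pmin(dims[2], index + band),
                     drop = FALSE]
    dose <- rowMeans(lines, na.rm = TRUE)
    n <- dims[1]
  }
  pos <- (seq_len(n) - (n + 1) / 2) * dm$mm_per_pixel
  out <- tibble::tibble(position_mm = pos, dose_gy = dose) |>
    dplyr::filter(!is.nan(.data$dose_gy))
  attr(out, "margin_mm") <- margin_mm
  out
}

#' Extract a dose profile from a film scan by pixel-space averaging
#'
#' The film readout averages pixel values over a region and converts the
#' mean pixel value to dose once (the ROI-mean method). For profiles this
#' means averaging the scan across a band of lines at each position and
#' converting each position's mean pixel through the curve. Compared with
#' converting pixelwise and averaging doses, this avoids two low-dose
#' biases near the unexposed end of the film: grain pushing single pixels
#' beyond the calibrated span (masking truncates the averaged tail) and the
#' curvature of the dose-of-pixel polynomial acting on per-pixel noise.
#'
#' @inheritParams profile_from_dose_map
#' @param scan A `film_scan`.
#' @param curve An `hd_curve`.
#' @return A tibble with `position_mm` and `dose_gy`; positions whose mean
#'   pixel falls outside the calibrated span are dropped.
#' @export
profile_from_scan <- function(scan, curve, axis = c("row", "col"),
                              index = NULL, band = 2L, margin_mm = NULL) {
  stopifnot(inherits(scan, "film_scan"), inherits(curve, "hd_curve"))
  axis <- match.arg(axis)
  dims <- dim(scan$pixels)
  if (axis == "row") {
    index <- index %||% round(dims[1] / 2)
    px <- colMeans(scan$pixels[pmax(1, index - band):pmin(dims[1], index + band), ,
                               drop = FALSE])
  } else {
    index <- index %||% round(dims[2] / 2)
    px <- rowMeans(scan$pixels[, pmax(1, index - band):pmin(dims[2], index + band),
                               drop = FALSE])
  }
  n <- length(px)
  pos <- (seq_len(n) - (n + 1) / 2) * scan$mm_per_pixel
  dose <- dose_from_pixel_masked(curve, px)
  out <- tibble::tibble(position_mm = pos, dose_gy = dose) |>
    dplyr::filter(!is.na(.data$dose_gy))
  attr(out, "margin_mm") <- margin_mm
  out
}

#' Write a dose map as 32-bit float TIFF plus JSON sidecar
#'
#' Doses are normalised by `dose_scale` for storage (float TIFF samples
#' live on [0, 1]); the scale, spatial calibration and mask encoding go to
#' the `<path>.json` sidecar. Masked pixels are stored as exactly 1.0,
#' above any real value.
#'
#' @param dm A `dose_map`.
#' @param path Output TIFF path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dose_map <- function(dm, path) {
  stopifnot(inherits(dm, "dose_map"))
  rng <- suppressWarnings(range(dm$dose, na.rm = TRUE))
  if (!all(is.finite(rng))) rng <- c(0, 1)
  # float TIFF samples live on [0, 1]: store (dose - offset) / scale with
  # the affine calibration in the sidecar (doses may dip slightly below 0)
  dose_offset <- min(0, rng[1])
  dose_scale <- max(rng[2] - dose_offset, .Machine$double.eps) * 1.01
  out <- (dm$dose - dose_offset) / dose_scale
  out[is.na(out)] <- 1
  tiff::writeTIFF(out, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(mm_per_pixel = dm$mm_per_pixel, film_model = dm$film_model,
         n_masked = dm$n_masked, units = "Gy", dose_scale = dose_scale,
         dose_offset = dose_offset, masked_value = 1),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_dose_map
#' @export
read_dose_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  raw <- tiff::readTIFF(path)
  dose <- raw * meta$dose_scale + (meta$dose_offset %||% 0)
  # float32 storage: compare to the mask sentinel with tolerance
  dose[abs(raw - meta$masked_value) < 1e-6] <- NA_real_
  structure(
    list(dose = dose, mm_per_pixel = meta$mm_per_pixel,
         film_model = meta$film_model, n_masked = sum(is.na(dose))),
    class = "dose_map"
  )
}

#' Plot a dose map
#'
#' @param object A `dose_map`.
#' @param ... Unused.
#' @return A ggplot raster of dose in Gy with mm axes.
#' @export
autoplot.dose_map <- function(object, ...) {
  dims <- dim(object$dose)
  df <- expand.grid(row = seq_len(dims[1]), col = seq_len(dims[2]))
  df$dose <- as.numeric(object$dose)
  df$x_mm <- (df$col - (dims[2] + 1) / 2) * object$mm_per_pixel
  df$y_mm <- -(df$row - (dims[1] + 1) / 2) * object$mm_per_pixel
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80", name = "Gy") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
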