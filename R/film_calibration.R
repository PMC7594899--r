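# Hunter-Driffield (HD) calibration: map mean red-channel pixel values of
# scanned radiochromic film to absorbed dose via a low-order polynomial.

#' Dynamic dose range of a supported radiochromic film model
#'
#' Two Gafchromic film models are supported: RTQA2 (0.02--8 Gy) and EBT-XD
#' (0.1--60 Gy). An unexposed-film point at 0 Gy is always permitted in
#' calibration sets; the range constrains positive doses.
#'
#' @param film_model `"RTQA2"` or `"EBT-XD"`.
#' @return Numeric length-2 vector `c(min_gy, max_gy)`.
#' @export
#' @examples
#' film_dynamic_range("EBT-XD")
film_dynamic_range <- function(film_model) {
  film_model <- match.arg(film_model, c("RTQA2", "EBT-XD"))
  switch(film_model, "RTQA2" = c(0.02, 8.0), "EBT-XD" = c(0.1, 60.0))
}

#' The standard calibration dose grid
#'
#' The discrete X-ray doses used to expose calibration film pieces:
#' 0, 0.1, 0.5, 1, 2.5, 3, 3.5, 4, 5, 6, 7, 10, 12, 15, 17, 20, 22, 24, 30
#' and 33 Gy. Individual experiments tailor a subset of this grid to their
#' working range.
#'
#' @return Numeric vector of doses in Gy.
#' @export
hd_dose_grid <- function() {
  c(0, 0.1, 0.5, 1, 2.5, 3, 3.5, 4, 5, 6, 7, 10, 12, 15, 17, 20, 22, 24, 30, 33)
}

validate_calibration_points <- function(points) {
  need <- c("dose_gy", "mean_pixel", "film_model")
  missing <- setdiff(need, names(points))
  if (length(missing) > 0) {
    stopf("calibration points must have columns: %s (missing: %s)",
          paste(need, collapse = ", "), paste(missing, collapse = ", "))
  }
  if (any(points$dose_gy < 0)) stopf("doses must be >= 0")
  if (any(points$mean_pixel < 0 | points$mean_pixel > 65535)) {
    stopf("mean_pixel values must lie on the 16-bit scale 0..65535")
  }
  fm <- unique(points$film_model)
  if (length(fm) != 1L) {
    stopf("all calibration points must share one film_model (got: %s)",
          paste(fm, collapse = ", "))
  }
  rng <- film_dynamic_range(fm)
  pos <- points$dose_gy[points$dose_gy > 0]
  if (any(pos < rng[1] | pos > rng[2])) {
    stopf("doses outside the %s dynamic range %.2f-%.1f Gy", fm, rng[1], rng[2])
  }
  invisible(points)
}

#' Fit a Hunter-Driffield calibration curve
#'
#' Fits absorbed dose as a third- or fourth-order polynomial in the mean
#' red-channel pixel value, by ordinary least squares. The fit direction is
#' dose-of-pixel so that converting a measured pixel value to dose is a single
#' polynomial evaluation with no numerical inversion. The fitted mapping must
#' be strictly monotone over the pixel span of the calibration points
#' (checked on a 1000-point grid); a non-monotone fit signals an unusable
#' calibration and is an error.
#'
#' @param points Data frame of calibration points with columns `dose_gy`,
#'   `mean_pixel` (16-bit scale, 0--65535) and `film_model` (`"RTQA2"` or
#'   `"EBT-XD"`); an `experiment_id` column is carried through if present.
#' @param order Polynomial order, 3 or 4, or `"auto"` to pick the order with
#'   the smaller leave-one-out RMS error.
#' @param guard_band Fractional widening of the calibrated pixel span within
#'   which [dose_from_pixel()] still evaluates (default 1%); beyond it,
#'   conversion is refused rather than extrapolated.
#' @return An object of class `hd_curve`: a list with `coefficients`
#'   (increasing powers of pixel), `order`, `dose_range`, `pixel_span`,
#'   `film_model`, `fit_residual` (root-mean-square relative residual over
#'   positive doses) and `direction = "dose_of_pixel"`.
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   dose_gy = c(0, 1, 2, 4, 6, 8),
#'   mean_pixel = 50000 - 4000 * c(0, 1, 2, 4, 6, 8),
#'   film_model = "RTQA2"
#' )
#' crv <- build_hd_curve(pts, order = 3)
#' dose_from_pixel(crv, 42000)
build_hd_curve <- function(points, order = "auto", guard_band = 0.01) {
  validate_calibration_points(points)
  if (identical(order, "auto")) {
    order <- pick_hd_order(points)
  }
  order <- as.integer(order)
  if (!order %in% c(3L, 4L)) stopf("order must be 3 or 4")
  n <- nrow(points)
  if (n < order + 2L) {
    stopf("too few calibration points: need at least %d for order %d, got %d",
          order + 2L, order, n)
  }

  px <- points$mean_pixel
  dose <- points$dose_gy
  fit <- stats::lm(dose ~ stats::poly(px, degree = order, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  coefs[is.na(coefs)] <- 0

  span <- range(px)
  grid <- seq(span[1], span[2], length.out = 1000L)
  vals <- polyval_inc(coefs, grid)
  dif <- diff(vals)
  if (!(all(dif > 0) || all(dif < 0))) {
    stopf("fitted dose-of-pixel mapping is not monotone over the calibrated pixel span; calibration unusable")
  }

  pos <- dose > 0
  fit_residual <- if (any(pos)) {
    sqrt(mean(((stats::fitted(fit)[pos] - dose[pos]) / dose[pos])^2))
  } else {
    NA_real_
  }

  structure(
    list(
      coefficients = coefs,
      order = order,
      dose_range = range(dose),
      pixel_span = span,
      film_model = unique(points$film_model),
      fit_residual = fit_residual,
      direction = "dose_of_pixel",
      guard_band = guard_band,
      n_points = n
    ),
    class = "hd_curve"
  )
}

# Leave-one-out RMS error of a dose-of-pixel polynomial fit of given order.
loo_rms <- function(points, order) {
  n <- nrow(points)
  if (n < order + 3L) return(Inf) # need a free point to leave out
  errs <- vapply(seq_len(n), function(i) {
    px <- points$mean_pixel[-i]
    dose <- points$dose_gy[-i]
    fit <- stats::lm(dose ~ stats::poly(px, degree = order, raw = TRUE))
    cf <- unname(stats::coef(fit))
    cf[is.na(cf)] <- 0
    polyval_inc(cf, points$mean_pixel[i]) - points$dose_gy[i]
  }, numeric(1))
  sqrt(mean(errs^2))
}

#' Choose the HD polynomial order by leave-one-out error
#'
#' Compares orders 3 and 4 by leave-one-out RMS prediction error on the
#' calibration points and returns the better order. Used by
#' [build_hd_curve()] when `order = "auto"`.
#'
#' @inheritParams build_hd_curve
#' @return 3 or 4.
#' @export
pick_hd_order <- function(points) {
  e3 <- loo_rms(points, 3L)
  e4 <- loo_rms(points, 4L)
  if (is.infinite(e3) && is.infinite(e4)) {
    stopf("too few calibration points for leave-one-out order selection")
  }
  if (e4 < e3) 4L else 3L
}

#' Convert mean pixel values to absorbed dose
#'
#' Evaluates the fitted dose-of-pixel polynomial. Pixel values outside the
#' calibrated span (widened by the curve's guard band) are refused with an
#' error -- radiochromic film saturates outside its dynamic range, so silent
#' extrapolation would fabricate doses. Results falling outside the curve's
#' calibrated dose range are clipped to that range and flagged with a
#' warning.
#'
#' @param curve An [build_hd_curve()] object.
#' @param mean_pixel Numeric vector of mean pixel values (16-bit scale).
#' @return Numeric vector of doses in Gy.
#' @export
dose_from_pixel <- function(curve, mean_pixel) {
  stopifnot(inherits(curve, "hd_curve"))
  span <- curve$pixel_span
  guard <- curve$guard_band * diff(span)
  lo <- span[1] - guard
  hi <- span[2] + guard
  out_of_span <- mean_pixel < lo | mean_pixel > hi
  if (any(out_of_span)) {
    stopf("pixel value(s) %s outside the calibrated span [%.0f, %.0f] (+/- %.0f%% guard band); refusing to extrapolate",
          paste(signif(mean_pixel[out_of_span][1], 6), collapse = ", "),
          span[1], span[2], 100 * curve$guard_band)
  }
  dose <- polyval_inc(curve$coefficients, mean_pixel)
  below <- dose < curve$dose_range[1]
  above <- dose > curve$dose_range[2]
  if (any(below | above)) {
    warnf("%d converted dose(s) fell outside the calibrated dose range [%.3g, %.3g] Gy and were clipped",
          sum(below | above), curve$dose_range[1], curve$dose_range[2])
    dose[below] <- curve$dose_range[1]
    dose[above] <- curve$dose_range[2]
  }
  dose
}

# Vectorised conversion that masks (returns NA) out-of-span pixels instead of
# erroring; used for pixelwise dose maps where shielded film is unexposed.
# In-span doses are NOT clipped to the calibrated dose range: clipping at the
# 0 Gy floor would truncate symmetric grain noise in shielded regions and
# bias their mean dose upward, so slightly negative per-pixel doses are kept
# and average out in region statistics.
dose_from_pixel_masked <- function(curve, mean_pixel) {
  span <- curve$pixel_span
  guard <- curve$guard_band * diff(span)
  ok <- mean_pixel >= span[1] - guard & mean_pixel <= span[2] + guard
  dose <- rep(NA_real_, length(mean_pixel))
  dose[ok] <- polyval_inc(curve$coefficients, mean_pixel[ok])
  dose
}

#' Inter-experiment deviation of calibration curves
#'
#' For each dose shared by at least three calibration experiments, computes
#' the percent deviation of every experiment's mean pixel value from the
#' cross-experiment mean at that dose. Doses measured by two or fewer
#' experiments are excluded. By construction the deviations at each dose
#' average to zero.
#'
#' @param points Data frame of calibration points from several experiments,
#'   with columns `dose_gy`, `mean_pixel` and `experiment_id`.
#' @return A tibble with columns `dose_gy`, `experiment_id`, `mean_pixel`,
#'   `cross_mean` and `deviation_pct`.
#' @export
curve_set_deviation <- function(points) {
  need <- c("dose_gy", "mean_pixel", "experiment_id")
  if (!all(need %in% names(points))) {
    stopf("need columns %s", paste(need, collapse = ", "))
  }
  if (dplyr::n_distinct(points$experiment_id) < 2L) {
    stopf("need at least two calibration experiments")
  }
  out <- points |>
    dplyr::group_by(.data$dose_gy) |>
    dplyr::filter(dplyr::n() > 2L) |>
    dplyr::mutate(
      cross_mean = mean(.data$mean_pixel),
      deviation_pct = 100 * (.data$mean_pixel / .data$cross_mean - 1)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("dose_gy", "experiment_id", "mean_pixel",
                  "cross_mean", "deviation_pct")
  if (nrow(out) == 0L) {
    stopf("no dose is shared by more than two experiments")
  }
  tibble::as_tibble(out)
}

#' @export
print.hd_curve <- function(x, ...) {
  cat(sprintf("<hd_curve> %s, order %d, %d points\n",
              x$film_model, x$order, x$n_points))
  cat(sprintf("  dose range: %.3g-%.3g Gy; pixel span: %.0f-%.0f\n",
              x$dose_range[1], x$dose_range[2],
              x$pixel_span[1], x$pixel_span[2]))
  cat(sprintf("  RMS relative residual: %.3g\n", x$fit_residual))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an HD calibration curve
#'
#' @param x An `hd_curve` object.
#' @param ... Unused.
#' @return A tibble with one row per polynomial term: `term` (power of the
#'   pixel value) and `estimate`.
#' @export
tidy.hd_curve <- function(x, ...) {
  tibble::tibble(
    term = paste0("pixel^", seq_along(x$coefficients) - 1L),
    estimate = x$coefficients
  )
}

#' One-row summary of an HD calibration curve
#'
#' @param x An `hd_curve` object.
#' @param ... Unused.
#' @return A one-row tibble with the film model, order, number of points,
#'   dose range and RMS relative residual.
#' @export
glance.hd_curve <- function(x, ...) {
  tibble::tibble(
    film_model = x$film_model,
    order = x$order,
    n_points = x$n_points,
    dose_min_gy = x$dose_range[1],
    dose_max_gy = x$dose_range[2],
    fit_residual = x$fit_residual
  )
}

#' Plot an HD curve against its calibration points
#'
#' Shows dose against mean pixel value with the fitted polynomial overlaid.
#'
#' @param object An `hd_curve` object.
#' @param points Optional data frame of calibration points to overplot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hd_curve <- function(object, points = NULL, ...) {
  grid <- tibble::tibble(
    mean_pixel = seq(object$pixel_span[1], object$pixel_span[2],
                     length.out = 400),
    dose_gy = polyval_inc(object$coefficients, seq(object$pixel_span[1],
                                                   object$pixel_span[2],
                                                   length.out = 400))
  )
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$mean_pixel,
                                          y = .data$dose_gy)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "mean red-channel pixel value", y = "dose (Gy)",
                  title = sprintf("HD curve (%s, order %d)",
                                  object$film_model, object$order))
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Read a calibration-point table from CSV
#'
#' Expects the header `dose_gy,mean_pixel,film_model,experiment_id`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of calibration points.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_calibration_points(df)
  tibble::as_tibble(df)
}

#' Write / read a fitted HD curve as JSON
#'
#' The JSON stores coefficients highest order first, the polynomial order,
#' dose range, pixel span, film model and RMS relative residual.
#'
#' @param curve An `hd_curve` object.
#' @param path Destination / source path.
#' @return `write_hd_curve()` returns `path` invisibly; `read_hd_curve()`
#'   returns an `hd_curve`.
#' @export
write_hd_curve <- function(curve, path) {
  stopifnot(inherits(curve, "hd_curve"))
  obj <- list(
    coefficients = rev(curve$coefficients), # highest order first
    order = curve$order,
    dose_range = curve$dose_range,
    pixel_span = curve$pixel_span,
    film_model = curve$film_model,
    fit_residual = curve$fit_residual,
    direction = curve$direction,
    guard_band = curve$guard_band,
    n_points = curve$n_points
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hd_curve
#' @export
read_hd_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      coefficients = rev(obj$coefficients),
      order = as.integer(obj$order),
      dose_range = obj$dose_range,
      pixel_span = obj$pixel_span,
      film_model = obj$film_model,
      fit_residual = obj$fit_residual,
      direction = obj$direction %||% "dose_of_pixel",
      guard_band = obj$guard_band %||% 0.01,
      n_points = obj$n_points %||% NA_integer_
    ),
    class = "hd_curve"
  )
}
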