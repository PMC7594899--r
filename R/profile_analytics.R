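# Dose-profile analytics: plateau normalisation, 80-20% penumbra, 50% field
# edges, tumour-margin offsets, out-of-field percent dose, site uniformity.

#' Build a dose-profile tibble
#'
#' A dose profile is a tibble of strictly increasing positions (mm) along a
#' named axis with the dose (Gy) at each position and, optionally, the
#' position of the tumour margin (the surface conforming to the inner
#' boundary of the mouse restraint at the tumour aperture).
#'
#' @param position_mm Strictly increasing numeric positions, mm.
#' @param dose_gy Dose at each position, Gy.
#' @param margin_mm Optional tumour-margin position.
#' @param axis_label Optional free-text axis description.
#' @return A tibble with attributes `margin_mm` and `axis_label`.
#' @export
dose_profile <- function(position_mm, dose_gy, margin_mm = NULL,
                         axis_label = NULL) {
  if (length(position_mm) != length(dose_gy)) {
    stopf("position_mm and dose_gy must have equal lengths")
  }
  if (any(diff(position_mm) <= 0)) {
    stopf("positions must be strictly increasing")
  }
  out <- tibble::tibble(position_mm = position_mm, dose_gy = dose_gy)
  attr(out, "margin_mm") <- margin_mm
  attr(out, "axis_label") <- axis_label
  out
}

profile_margin <- function(profile, margin_mm = NULL) {
  margin_mm %||% attr(profile, "margin_mm")
}

dose_col <- function(profile) {
  if ("dose_pct" %in% names(profile)) "dose_pct" else "dose_gy"
}

#' Normalise a profile to percent of its plateau mean
#'
#' Divides doses by the mean over a plateau window and rescales to percent,
#' so that the 80/20/50% levels used for penumbra and field-edge analysis
#' are defined. Normalising an already-normalised profile again over the
#' same window is the identity (idempotent).
#'
#' @param profile A profile tibble (`position_mm`, `dose_gy` or `dose_pct`).
#' @param plateau_window Length-2 numeric range in mm over which to average;
#'   must contain at least 3 samples. Defaults to the central fifth of the
#'   profile extent.
#' @return A tibble with `position_mm` and `dose_pct`; the plateau mean (in
#'   the input's units) is attached as attribute `plateau_mean`; margin and
#'   axis attributes are carried over.
#' @export
normalize_profile <- function(profile, plateau_window = NULL) {
  dc <- dose_col(profile)
  x <- profile$position_mm
  if (is.null(plateau_window)) {
    mid <- (min(x) + max(x)) / 2
    half <- diff(range(x)) / 10
    plateau_window <- c(mid - half, mid + half)
  }
  inside <- x >= plateau_window[1] & x <= plateau_window[2]
  if (sum(inside) < 3L) {
    stopf("plateau window [%g, %g] mm contains %d samples; need >= 3",
          plateau_window[1], plateau_window[2], sum(inside))
  }
  plateau_mean <- mean(profile[[dc]][inside])
  if (plateau_mean == 0) stopf("plateau mean is zero; cannot normalise")
  out <- tibble::tibble(
    position_mm = x,
    dose_pct = 100 * profile[[dc]] / plateau_mean
  )
  attr(out, "plateau_mean") <- plateau_mean
  attr(out, "margin_mm") <- attr(profile, "margin_mm")
  attr(out, "axis_label") <- attr(profile, "axis_label")
  out
}

# Find the outermost crossing of `level` on one edge of a normalised
# profile. Starting from the plateau sample nearest the profile centre, walk
# outward and take the first bracketing interval. Returns NA when the level
# is never crossed on that side.
edge_crossing <- function(x, y, level, side = c("left", "right")) {
  side <- match.arg(side)
  centre <- which.max(y > max(y) * 0.9)[1]
  # walk from the highest plateau region outward
  peak <- which.max(y)
  idx <- if (side == "left") rev(seq_len(peak - 1L)) else peak:(length(y) - 1L)
  for (i in idx) {
    lo <- min(y[i], y[i + 1L])
    hi <- max(y[i], y[i + 1L])
    if (level >= lo && level <= hi) {
      return(cross_between(x, y, level, i))
    }
  }
  NA_real_
}

#' 80-20% penumbra width of each field edge
#'
#' The penumbra is the lateral distance over which the profile falls from
#' `hi`% to `lo`% of the plateau (80% and 20% by convention). Crossing
#' positions are found by walking outward from the plateau and linearly
#' interpolating between adjacent samples; the width on each edge is
#' `|x(lo) - x(hi)|`. An edge that never crosses a level is reported as
#' `NA` with a warning rather than failing the whole profile.
#'
#' @param profile A normalised profile (see [normalize_profile()]); a
#'   profile in Gy is normalised on the fly with the default window.
#' @param hi,lo Upper and lower levels in percent (defaults 80 and 20).
#' @return A tibble with one row per edge: `edge`, `x_hi_mm`, `x_lo_mm`,
#'   `width_mm`.
#' @export
penumbra_width <- function(profile, hi = 80, lo = 20) {
  if (!"dose_pct" %in% names(profile)) profile <- normalize_profile(profile)
  x <- profile$position_mm
  y <- profile$dose_pct
  rows <- lapply(c("left", "right"), function(side) {
    x_hi <- edge_crossing(x, y, hi, side)
    x_lo <- edge_crossing(x, y, lo, side)
    if (is.na(x_hi) || is.na(x_lo)) {
      warnf("%s edge does not cross both the %g%% and %g%% levels", side, hi, lo)
    }
    tibble::tibble(edge = side, x_hi_mm = x_hi, x_lo_mm = x_lo,
                   width_mm = abs(x_lo - x_hi))
  })
  dplyr::bind_rows(rows)
}

#' 50% field-edge positions
#'
#' Positions where the normalised profile crosses `level`% (50% by the
#' standard field-size convention) on each side of the plateau.
#'
#' @inheritParams penumbra_width
#' @param level Crossing level in percent (default 50).
#' @return A tibble with `left_mm` and `right_mm`.
#' @export
field_edge_positions <- function(profile, level = 50) {
  if (!"dose_pct" %in% names(profile)) profile <- normalize_profile(profile)
  x <- profile$position_mm
  y <- profile$dose_pct
  left <- edge_crossing(x, y, level, "left")
  right <- edge_crossing(x, y, level, "right")
  if (is.na(left) && is.na(right)) {
    stopf("profile never crosses the %g%% level on either side (all-plateau or all-tail profile)", level)
  }
  tibble::tibble(left_mm = left, right_mm = right)
}

#' Signed offset of the exposure edge from the tumour margin
#'
#' Finds where the profile crosses `threshold`% of the plateau nearest to
#' the marked tumour-margin position and reports the signed distance from
#' the margin. Sign convention: positive means the exposure edge sits on the
#' tumour (in-field) side of the margin; negative means the field spills
#' into the shielded side.
#'
#' @param profile A profile with a margin (attribute `margin_mm` or the
#'   `margin_mm` argument).
#' @param threshold Edge-defining level in percent of plateau (default 50).
#' @param margin_mm Margin position, overriding the profile attribute.
#' @return Signed distance in mm (scalar).
#' @export
margin_offset <- function(profile, threshold = 50, margin_mm = NULL) {
  margin <- profile_margin(profile, margin_mm)
  if (is.null(margin)) stopf("no tumour-margin position on this profile")
  if (!"dose_pct" %in% names(profile)) profile <- normalize_profile(profile)
  x <- profile$position_mm
  y <- profile$dose_pct
  xl <- edge_crossing(x, y, threshold, "left")
  xr <- edge_crossing(x, y, threshold, "right")
  cand <- c(xl, xr)
  if (all(is.na(cand))) stopf("profile never crosses the %g%% threshold", threshold)
  x_cross <- cand[which.min(abs(cand - margin))]
  # in-field side: for the left edge the field lies to the right, so an edge
  # at x_cross > margin is inside the tumour side; mirrored for the right edge
  if (!is.na(xl) && isTRUE(all.equal(x_cross, xl))) {
    x_cross - margin
  } else {
    margin - x_cross
  }
}

#' Dose at a position as percent of a reference
#'
#' Linearly interpolates the profile at `position_mm` and expresses it as a
#' percentage of `reference_gy` (e.g. the prescribed tumour dose).
#'
#' @param profile A profile in Gy.
#' @param position_mm Position to evaluate.
#' @param reference_gy Reference dose; must be non-zero.
#' @return Percent of reference (scalar).
#' @export
percent_dose_at <- function(profile, position_mm, reference_gy) {
  if (reference_gy == 0) stopf("reference dose must be non-zero")
  dc <- dose_col(profile)
  d <- stats::approx(profile$position_mm, profile[[dc]],
                     xout = position_mm, rule = 1)$y
  if (any(is.na(d))) stopf("position outside the profile extent")
  100 * d / reference_gy
}

#' Dose uniformity across restraint sites
#'
#' Summarises the doses delivered at the restraint positions of the jig:
#' mean, standard error of the mean as percent of the mean, and the maximum
#' absolute deviation from the mean as percent. SEM% and max-deviation% are
#' distinct uniformity metrics and both are reported.
#'
#' @param site_doses Numeric vector of site doses in Gy (typically 5, one
#'   per restraint), or a data frame with a `dose_gy` column.
#' @return A one-row tibble: `n`, `mean_gy`, `sem_percent`,
#'   `max_abs_dev_percent`.
#' @export
site_uniformity <- function(site_doses) {
  if (is.data.frame(site_doses)) site_doses <- site_doses$dose_gy
  n <- length(site_doses)
  if (n < 2L) stopf("need at least two site doses")
  m <- mean(site_doses)
  sem <- stats::sd(site_doses) / sqrt(n)
  tibble::tibble(
    n = n,
    mean_gy = m,
    sem_percent = 100 * sem / m,
    max_abs_dev_percent = 100 * max(abs(site_doses - m)) / m
  )
}

#' Full metric set for one profile
#'
#' Convenience wrapper returning plateau mean, 50% edges, per-edge 80-20%
#' penumbrae, flatness over the field core, and the margin offset when a
#' margin is marked.
#'
#' @param profile A profile in Gy.
#' @param plateau_window Passed to [normalize_profile()].
#' @param core_fraction Fraction of the 50%-edge field width treated as the
#'   field core for the flatness metric (default 0.8).
#' @return A one-row tibble of metrics.
#' @export
profile_metrics <- function(profile, plateau_window = NULL,
                            core_fraction = 0.8) {
  norm <- normalize_profile(profile, plateau_window)
  edges <- field_edge_positions(norm)
  pen <- penumbra_width(norm)
  core_half <- core_fraction * (edges$right_mm - edges$left_mm) / 2
  centre <- (edges$right_mm + edges$left_mm) / 2
  core <- norm$dose_pct[abs(norm$position_mm - centre) <= core_half]
  flat <- if (length(core) > 0) max(abs(core - 100)) else NA_real_
  margin <- profile_margin(profile)
  tibble::tibble(
    plateau_mean_gy = attr(norm, "plateau_mean"),
    edge_50_left_mm = edges$left_mm,
    edge_50_right_mm = edges$right_mm,
    penumbra_80_20_left_mm = pen$width_mm[pen$edge == "left"],
    penumbra_80_20_right_mm = pen$width_mm[pen$edge == "right"],
    flatness_percent = flat,
    margin_offset_mm = if (is.null(margin)) NA_real_ else
      margin_offset(profile, margin_mm = margin)
  )
}

#' Read / write profile CSV
#'
#' Profiles are stored as CSV with header `position_mm,dose_gy`; the tumour
#' margin, when present, is a comment line `# margin_mm: <value>` above the
#' header.
#'
#' @param path File path.
#' @return A profile tibble with the `margin_mm` attribute set when present.
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  margin <- NULL
  m <- grep("^#\\s*margin_mm:", lines, value = TRUE)
  if (length(m) > 0) margin <- as.numeric(sub("^#\\s*margin_mm:\\s*", "", m[1]))
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  dose_profile(df$position_mm, df$dose_gy, margin_mm = margin)
}

#' @rdname read_profile_csv
#' @param profile A profile tibble.
#' @export
write_profile_csv <- function(profile, path) {
  margin <- attr(profile, "margin_mm")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(margin)) writeLines(sprintf("# margin_mm: %.6g", margin), con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE)
  invisible(path)
}

#' Plot a dose profile with its metrics
#'
#' @param profile A profile in Gy (or normalised).
#' @param show_margin Draw the tumour margin when marked.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, show_margin = TRUE) {
  dc <- dose_col(profile)
  ylab <- if (dc == "dose_pct") "dose (% of plateau)" else "dose (Gy)"
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$position_mm, y = .data[[dc]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (mm)", y = ylab,
                  title = attr(profile, "axis_label"))
  margin <- attr(profile, "margin_mm")
  if (show_margin && !is.null(margin)) {
    p <- p + ggplot2::geom_vline(xintercept = margin, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}
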