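# Synthetic-data generators: film response curves, 2-D beam dose fields,
# rendered film scans, phantom site exposures and tumour-growth datasets.
# Every generator returns its ground truth alongside the data so recovery
# tests compare estimates against known truth, and all randomness flows
# from one explicit seed per call.

# Run code with a locally set seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Synthetic film response model
#'
#' A monotone forward model pixel(dose) for a radiochromic film: the mean
#' red-channel pixel value falls from an unexposed plateau as dose
#' increases. The default forward function is a fourth-order polynomial
#' fitted to anchor points of an exponential-saturation response
#' `pixel_min + (pixel_max - pixel_min) * exp(-dose / tau)` over the film's
#' dynamic range, with strict monotonicity verified on a fine grid. Noise
#' has two components mirroring real film work: per-point multiplicative
#' scanner grain, and a per-sheet (batch) offset common to all points of
#' one experiment, at the few-percent scale seen between calibration
#' batches.
#'
#' @param film_model `"RTQA2"` or `"EBT-XD"`.
#' @param noise_sigma_rel Relative SD of per-point noise on calibration
#'   mean-pixel values. A calibration point is a 50 x 50 ROI mean, so its
#'   grain-driven standard error is the per-pixel grain over 50 (0.02% at
#'   1%/pixel); the default 0.001 allows for that plus film-piece
#'   non-uniformity. Per-pixel grain in rendered images is set separately
#'   in [render_film()].
#' @param batch_sigma_rel Relative SD of the per-sheet batch offset
#'   (default 0.025, the observed inter-experiment scale).
#' @param pixel_max,pixel_min Unexposed and saturated pixel levels.
#' @param tau_gy Exponential dose constant of the anchor response; defaults
#'   to one third of the film's maximum dose.
#' @return A `film_response_model` with the forward polynomial coefficients
#'   (increasing powers of dose), the dose range and the noise parameters.
#' @export
film_response_model <- function(film_model = c("EBT-XD", "RTQA2"),
                                noise_sigma_rel = 0.001,
                                batch_sigma_rel = 0.025,
                                pixel_max = 58000, pixel_min = 12000,
                                tau_gy = NULL) {
  film_model <- match.arg(film_model)
  rng <- film_dynamic_range(film_model)
  tau_gy <- tau_gy %||% (rng[2] / 3)
  d <- seq(0, rng[2], length.out = 121L)
  anchor <- pixel_min + (pixel_max - pixel_min) * exp(-d / tau_gy)
  fit <- stats::lm(anchor ~ stats::poly(d, 4, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  grid <- seq(0, rng[2], length.out = 1000L)
  if (!all(diff(polyval_inc(coefs, grid)) < 0)) {
    stopf("forward film response is not strictly decreasing over 0-%g Gy; adjust tau_gy", rng[2])
  }
  structure(
    list(
      film_model = film_model,
      forward_coefs = coefs,
      dose_range = rng,
      noise_sigma_rel = noise_sigma_rel,
      batch_sigma_rel = batch_sigma_rel,
      pixel_max = pixel_max,
      pixel_min = pixel_min,
      tau_gy = tau_gy
    ),
    class = "film_response_model"
  )
}

#' Noiseless forward film response
#'
#' @param model A [film_response_model()].
#' @param dose_gy Doses in Gy, within `[0, max range]`.
#' @return Mean pixel values on the 16-bit scale.
#' @export
film_response_pixel <- function(model, dose_gy) {
  stopifnot(inherits(model, "film_response_model"))
  if (any(dose_gy < 0 | dose_gy > model$dose_range[2])) {
    stopf("dose outside the %s film range 0-%g Gy", model$film_model,
          model$dose_range[2])
  }
  polyval_inc(model$forward_coefs, dose_gy)
}

#' Simulate one Hunter-Driffield calibration experiment
#'
#' Exposes virtual film pieces to the given doses and returns their mean
#' pixel values with one per-sheet batch offset and per-point grain.
#'
#' @param doses Doses in Gy (default the standard grid restricted to the
#'   film range); positive doses above the film's dynamic range are an
#'   error.
#' @param model A [film_response_model()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param experiment_id Label for the `experiment_id` column.
#' @return A calibration tibble (`dose_gy`, `mean_pixel`, `film_model`,
#'   `experiment_id`) with the batch offset as attribute `batch_offset`.
#' @export
simulate_hd_response <- function(doses = NULL, model = film_response_model(),
                                 seed = NULL, experiment_id = "sim-1") {
  doses <- doses %||% hd_dose_grid()[hd_dose_grid() <= model$dose_range[2]]
  pixel0 <- film_response_pixel(model, doses)
  with_local_seed(seed, {
    batch <- stats::rnorm(1, 0, model$batch_sigma_rel)
    grain <- stats::rnorm(length(doses), 0, model$noise_sigma_rel)
    px <- pixel0 * (1 + batch) * (1 + grain)
    out <- tibble::tibble(
      dose_gy = doses,
      mean_pixel = pmin(pmax(px, 0), 65535),
      film_model = model$film_model,
      experiment_id = experiment_id
    )
    attr(out, "batch_offset") <- batch
    out
  })
}

#' Simulate a set of replicate calibration experiments
#'
#' @inheritParams simulate_hd_response
#' @param n_curves Number of replicate experiments.
#' @return A single calibration tibble with `experiment_id` distinguishing
#'   the replicates.
#' @export
simulate_hd_experiments <- function(n_curves, doses = NULL,
                                    model = film_response_model(),
                                    seed = NULL) {
  with_local_seed(seed, {
    purrr::map_dfr(seq_len(n_curves), function(k) {
      simulate_hd_response(doses, model, seed = NULL,
                           experiment_id = sprintf("sim-%d", k))
    })
  })
}

#' Synthetic beam-field model
#'
#' Describes a rectangular tangential field over the tumour aperture with
#' error-function edges and a uniform shielded leakage floor. The analytic
#' 80-20% penumbra width of an erf edge with spread `sigma` is
#' `(qnorm(0.8) - qnorm(0.2)) * sigma = 1.683 sigma`; the default
#' `edge_sigma_mm = 1.188` therefore gives the commissioned ~2 mm penumbra.
#' The default leakage fraction 0.008 is the 7-HVL narrow-beam transmission
#' level.
#'
#' @param field_span_mm Field width between 50% edges (default 10, the
#'   tumour aperture).
#' @param edge_sigma_mm Erf edge spread, mm.
#' @param plateau_dose_gy In-field plateau dose, Gy.
#' @param leakage_fraction Shielded-floor dose as a fraction of plateau.
#' @param margin_mm Tumour-margin position; defaults to the left 50% edge
#'   (`-field_span_mm / 2`).
#' @param edge_offset_mm Shift of the whole field relative to the margin
#'   (positive moves the field edge toward the tumour side).
#' @return A `field_model` list.
#' @export
field_model <- function(field_span_mm = 10, edge_sigma_mm = 1.188,
                        plateau_dose_gy = 5, leakage_fraction = 0.008,
                        margin_mm = NULL, edge_offset_mm = 0) {
  structure(
    list(
      field_span_mm = field_span_mm,
      edge_sigma_mm = edge_sigma_mm,
      plateau_dose_gy = plateau_dose_gy,
      leakage_fraction = leakage_fraction,
      margin_mm = margin_mm %||% (-field_span_mm / 2),
      edge_offset_mm = edge_offset_mm
    ),
    class = "field_model"
  )
}

erf_field_1d <- function(x, centre, span, sigma) {
  if (span <= 0) return(rep(0, length(x)))
  if (sigma <= 0) {
    return(as.numeric(abs(x - centre) <= span / 2))
  }
  stats::pnorm((x - (centre - span / 2)) / sigma) -
    stats::pnorm((x - (centre + span / 2)) / sigma)
}

#' Simulate a 2-D beam dose field
#'
#' Renders the separable erf-edged field of a [field_model()] on a regular
#' grid and returns the dose matrix together with the analytic ground-truth
#' metrics (penumbra width, 50% edges, plateau and leakage doses).
#'
#' @param model A [field_model()].
#' @param grid_mm_per_px Grid spacing (default 25.4/600, i.e. 600 dpi).
#' @param extent_mm Half-extent of the map in mm (default field span/2 +
#'   8 mm of shielded surround).
#' @return A list with `dose` (matrix, rows = y top-down, cols = x),
#'   `mm_per_pixel`, `x_mm`, `y_mm` and `truth` (list of analytic metrics).
#' @export
simulate_beam_field <- function(model, grid_mm_per_px = 25.4 / 600,
                                extent_mm = NULL) {
  stopifnot(inherits(model, "field_model"))
  extent_mm <- extent_mm %||% (model$field_span_mm / 2 + 8)
  x <- seq(-extent_mm, extent_mm, by = grid_mm_per_px)
  y <- x
  centre <- model$margin_mm + model$field_span_mm / 2 + model$edge_offset_mm
  fx <- erf_field_1d(x, centre, model$field_span_mm, model$edge_sigma_mm)
  fy <- erf_field_1d(y, 0, model$field_span_mm, model$edge_sigma_mm)
  open_frac <- outer(fy, fx) # rows = y, cols = x
  dose <- model$plateau_dose_gy *
    (model$leakage_fraction + (1 - model$leakage_fraction) * open_frac)
  width_8020 <- (stats::qnorm(0.8) - stats::qnorm(0.2)) * model$edge_sigma_mm
  list(
    dose = dose,
    mm_per_pixel = grid_mm_per_px,
    x_mm = x,
    y_mm = y,
    truth = list(
      plateau_dose_gy = model$plateau_dose_gy,
      leakage_dose_gy = model$plateau_dose_gy * model$leakage_fraction,
      leakage_fraction = model$leakage_fraction,
      penumbra_80_20_mm = width_8020,
      edge_50_left_mm = centre - model$field_span_mm / 2,
      edge_50_right_mm = centre + model$field_span_mm / 2,
      margin_mm = model$margin_mm,
      margin_offset_mm = model$edge_offset_mm
    )
  )
}

#' Render a dose field as a scanned-film image
#'
#' Inverse of the measurement chain: converts a dose matrix to red-channel
#' pixel values through the forward film response, applies one per-sheet
#' batch offset and per-pixel multiplicative grain, rounds to integers on
#' the 16-bit scale and (optionally) writes a 16-bit grayscale TIFF with a
#' JSON sidecar carrying the dpi and film model. Rendering is
#' bit-reproducible for a fixed seed.
#'
#' @param dose Dose matrix in Gy (e.g. from [simulate_beam_field()]), or a
#'   list with a `dose` element.
#' @param model A [film_response_model()].
#' @param dpi Scan resolution (default 600).
#' @param seed Integer seed for batch and grain noise; `NULL` for noiseless
#'   rendering.
#' @param pixel_sigma_rel Per-pixel grain SD (default 0.01).
#' @param path Optional output TIFF path; when given, the image and its
#'   `<path>.json` sidecar are written.
#' @return A `film_scan` (invisibly when `path` is given).
#' @export
render_film <- function(dose, model = film_response_model(), dpi = 600,
                        seed = NULL, pixel_sigma_rel = 0.01, path = NULL) {
  if (is.list(dose) && !is.null(dose$dose)) dose <- dose$dose
  stopifnot(is.matrix(dose))
  px0 <- film_response_pixel(model, as.numeric(dose))
  px <- with_local_seed(seed, {
    if (is.null(seed)) {
      px0
    } else {
      batch <- stats::rnorm(1, 0, model$batch_sigma_rel)
      grain <- stats::rnorm(length(px0), 0, pixel_sigma_rel)
      px0 * (1 + batch) * (1 + grain)
    }
  })
  px <- matrix(round(pmin(pmax(px, 0), 65535)), nrow = nrow(dose))
  scan <- new_film_scan(px, dpi = dpi, channels = "red-only",
                        film_model = model$film_model)
  if (!is.null(path)) {
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    jsonlite::write_json(
      list(dpi = dpi, film_model = model$film_model, bits = 16,
           channels = "red-only", synthetic = TRUE),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
    return(invisible(scan))
  }
  scan
}

#' Simulate a wax-phantom exposure
#'
#' Evaluates the analytical jig model at the six instrumented sites of the
#' mouse phantom: film inserts at the dorsal, midline and ventral positions
#' of the protruding tumour, and at the shielded head, body and rear. Each
#' of the two opposed tangents (15 and 195 degrees) contributes an
#' exponential depth dose through the tumour (the 15-degree beam enters
#' dorsally, the 195-degree beam ventrally), with per-beam entry doses set
#' by [parallel_opposed_midline()] so that the prescription is met at the
#' tumour midline. Shielded sites receive the narrow-beam shield
#' transmission plus the configured scatter fraction. Optional multiplicative
#' jitter emulates setup and film variability.
#'
#' @param config A [default_sarj_config()]-style configuration.
#' @param prescription_gy Total midline prescription, Gy.
#' @param site_jitter_rel Relative SD of per-site, per-beam multiplicative
#'   jitter (default 0, deterministic).
#' @param seed Integer seed used when `site_jitter_rel > 0`.
#' @return A tibble with `site`, `angle_deg`, `dose_gy`, plus the
#'   deterministic model doses in attribute `truth`.
#' @export
simulate_phantom_exposure <- function(config = default_sarj_config(),
                                      prescription_gy = 12,
                                      site_jitter_rel = 0, seed = NULL) {
  mu <- config$depth_dose$mu_eff_per_mm
  thick <- config$depth_dose$body_thickness_mm
  entry <- parallel_opposed_midline(prescription_gy, thick, mu)$entry_dose_gy
  shield <- config_shield(config)
  scatter <- config$scatter_fraction %||% 0
  shielded_per_beam <- leakage_dose(prescription_gy / 2, shield, scatter)

  tumour_depths <- c(tumour_dorsal = 0, tumour_mid = thick / 2,
                     tumour_ventral = thick)
  rows <- list()
  for (angle in config$beam$angles_deg) {
    depths <- if (angle == config$beam$angles_deg[1]) tumour_depths else
      rev(unname(tumour_depths))
    tum <- depth_dose(entry, unname(depths), mu)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      site = c(names(tumour_depths), "head", "body", "rear"),
      angle_deg = angle,
      dose_gy = c(tum, rep(shielded_per_beam, 3L))
    )
  }
  out <- dplyr::bind_rows(rows)
  truth <- out
  if (site_jitter_rel > 0) {
    out$dose_gy <- with_local_seed(seed, {
      out$dose_gy * (1 + stats::rnorm(nrow(out), 0, site_jitter_rel))
    })
  }
  attr(out, "truth") <- truth
  attr(out, "entry_dose_gy") <- entry
  out
}

#' Synthetic tumour-growth model
#'
#' Exponential growth with a radiation-induced regression-and-recurrence
#' phase: each fraction multiplies the volume by `1 - kill_fraction`;
#' growth is arrested for `regrowth_delay_days` after the last fraction and
#' then resumes at the animal's own rate. Defaults emulate day-8 flank
#' melanomas of 8 x 8 mm (256 mm^3) growing at 0.22/day, treated on three
#' consecutive days, with a ~10-day response before recurrence, and a
#' humane-endpoint volume of 1000 mm^3.
#'
#' @param v0_mm3 Volume at the first measurement day.
#' @param growth_rate_per_day Exponential growth rate.
#' @param kill_fraction_per_fraction Fractional cell kill per fraction.
#' @param regrowth_delay_days Growth-arrest period after the last fraction.
#' @param endpoint_volume_mm3 Humane-endpoint volume.
#' @param rate_sigma_rel Lognormal SD of per-animal growth rates.
#' @param measure_sigma_rel Relative SD of calliper measurement noise.
#' @return A `growth_model` list.
#' @export
growth_model <- function(v0_mm3 = 256, growth_rate_per_day = 0.22,
                         kill_fraction_per_fraction = 0.7,
                         regrowth_delay_days = 10,
                         endpoint_volume_mm3 = 1000,
                         rate_sigma_rel = 0.2, measure_sigma_rel = 0.05) {
  structure(
    list(
      v0_mm3 = v0_mm3, growth_rate_per_day = growth_rate_per_day,
      kill_fraction_per_fraction = kill_fraction_per_fraction,
      regrowth_delay_days = regrowth_delay_days,
      endpoint_volume_mm3 = endpoint_volume_mm3,
      rate_sigma_rel = rate_sigma_rel,
      measure_sigma_rel = measure_sigma_rel
    ),
    class = "growth_model"
  )
}

#' Simulate a two-group tumour-growth study
#'
#' Generates per-animal calliper time series for an irradiated and a
#' control group under a [growth_model()]. Tumours are measured every two
#' days from the first treatment day until the study end; an animal reaches
#' its event on the first measurement day its volume is at or above the
#' endpoint volume, after which it stops contributing measurements; animals
#' alive at the study end are censored there. Calliper width and length are
#' back-computed from volume assuming a roughly isotropic tumour
#' (`W = L = (2V)^(1/3)`) with independent measurement noise on each axis.
#'
#' @param model A [growth_model()].
#' @param schedule_days Treatment (fraction) days (default `c(8, 9, 10)`).
#' @param n_per_group Animals per group (default 6).
#' @param start_day First measurement day (default 8).
#' @param end_day Study end / censoring day (default 35).
#' @param seed Integer seed.
#' @return A tibble with `animal_id`, `group`, `day`, `width_mm`,
#'   `length_mm`, `volume_mm3`, `event_day`, `event`; the noiseless
#'   per-animal trajectories are attached as attribute `truth`.
#' @export
simulate_tumour_growth <- function(model = growth_model(),
                                   schedule_days = c(8, 9, 10),
                                   n_per_group = 6, start_day = 8,
                                   end_day = 35, seed = NULL) {
  stopifnot(inherits(model, "growth_model"))
  measure_days <- unique(c(seq(start_day, end_day, by = 2), end_day))
  last_fraction <- max(schedule_days)

  simulate_animal <- function(id, group) {
    rate <- model$growth_rate_per_day *
      exp(stats::rnorm(1, 0, model$rate_sigma_rel))
    v0 <- model$v0_mm3 * exp(stats::rnorm(1, 0, model$rate_sigma_rel / 2))
    treated <- group == "irradiated"
    days <- start_day:end_day
    v <- numeric(length(days))
    v[1] <- v0
    if (treated && start_day %in% schedule_days) {
      v[1] <- v[1] * (1 - model$kill_fraction_per_fraction)
    }
    for (i in seq_along(days)[-1]) {
      day <- days[i]
      growing <- !treated || day < min(schedule_days) ||
        day > last_fraction + model$regrowth_delay_days
      v[i] <- v[i - 1] * exp(if (growing) rate else 0)
      if (treated && day %in% schedule_days) {
        v[i] <- v[i] * (1 - model$kill_fraction_per_fraction)
      }
    }
    traj <- tibble::tibble(animal_id = id, group = group, day = days,
                           true_volume_mm3 = v)
    meas <- traj[traj$day %in% measure_days, ]
    wl <- (2 * meas$true_volume_mm3)^(1 / 3)
    width <- wl * (1 + stats::rnorm(nrow(meas), 0, model$measure_sigma_rel))
    length_ <- wl * (1 + stats::rnorm(nrow(meas), 0, model$measure_sigma_rel))
    vol <- tumour_volume(width, length_)
    hit <- which(vol >= model$endpoint_volume_mm3)
    event <- length(hit) > 0
    event_day <- if (event) meas$day[hit[1]] else end_day
    keep <- meas$day <= event_day
    list(
      records = tibble::tibble(
        animal_id = id, group = group, day = meas$day[keep],
        width_mm = width[keep], length_mm = length_[keep],
        volume_mm3 = vol[keep], event_day = event_day, event = event
      ),
      truth = traj
    )
  }

  with_local_seed(seed, {
    ids <- c(sprintf("ctrl-%02d", seq_len(n_per_group)),
             sprintf("irr-%02d", seq_len(n_per_group)))
    groups <- rep(c("control", "irradiated"), each = n_per_group)
    sims <- purrr::map2(ids, groups, simulate_animal)
    out <- purrr::map_dfr(sims, "records")
    attr(out, "truth") <- purrr::map_dfr(sims, "truth")
    out
  })
}
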