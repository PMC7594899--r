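test_that("noiseless exact-degree fit reproduces the generating cubic", {
  pts <- exact_cubic_points()
  crv <- build_hd_curve(pts, order = 3)
  # predictions at off-knot pixels match the generating relation
  px_new <- seq(21000, 55000, length.out = 40)
  expect_equal(dose_from_pixel(crv, px_new), exact_cubic_dose(px_new),
               tolerance = 1e-8)
  expect_lt(crv$fit_residual, 1e-10)
  # interpolation at a knot of an exact fit returns the knot dose
  i <- which.min(abs(pts$dose_gy - 5))
  expect_equal(dose_from_pixel(crv, pts$mean_pixel[i]), pts$dose_gy[i],
               tolerance = 1e-10)
})

test_that("noisy quartic calibration recovers doses within tolerance", {
  model <- film_response_model("EBT-XD", noise_sigma_rel = 0.01,
                               batch_sigma_rel = 0)
  doses <- c(2.5, 4, 6, 9, 13, 18, 24, 30, 36, 45)
  pts <- simulate_hd_response(doses, model, seed = 11)
  crv <- build_hd_curve(pts, order = 4)
  est <- dose_from_pixel(crv, pts$mean_pixel)
  expect_lt(median(abs(est - doses) / doses), 0.025)
})

test_that("degrees-of-freedom and range violations are errors", {
  pts <- exact_cubic_points(n = 3)
  expect_error(build_hd_curve(pts, order = 4), "too few")
  bad <- tibble::tibble(dose_gy = c(0, 1, 5, 9), # 9 Gy beyond RTQA2 range
                        mean_pixel = c(50000, 40000, 30000, 20000),
                        film_model = "RTQA2")
  expect_error(build_hd_curve(bad, order = 3), "dynamic range")
  mixed <- exact_cubic_points()
  mixed$film_model[1] <- "RTQA2"
  expect_error(build_hd_curve(mixed, order = 3), "film_model")
})

test_that("a non-monotone fitted mapping is rejected as unusable", {
  # pixel values folding back on themselves force a non-monotone polynomial
  px <- c(20000, 30000, 40000, 50000, 30500, 21000)
  pts <- tibble::tibble(dose_gy = c(33, 20, 10, 3, 25, 31),
                        mean_pixel = px, film_model = "EBT-XD")
  expect_error(build_hd_curve(pts, order = 4), "monotone")
})

test_that("conversion refuses to extrapolate beyond the guard band", {
  crv <- build_hd_curve(exact_cubic_points(), order = 3)
  hi <- crv$pixel_span[2]
  expect_error(dose_from_pixel(crv, hi * 1.10), "extrapolat|span")
  # inside the 1% guard band still evaluates; the slightly out-of-range
  # dose is clipped to the calibrated range and flagged
  expect_warning(
    d <- dose_from_pixel(crv, hi + 0.009 * diff(crv$pixel_span)),
    "clipped"
  )
  expect_equal(d, crv$dose_range[1])
})

test_that("round trip over random doses has small median relative error", {
  model <- film_response_model("EBT-XD")
  cal <- simulate_hd_response(model = model, seed = 3)
  crv <- build_hd_curve(cal, order = 4)
  set.seed(301)
  doses <- runif(100, 0.5, 33)
  # measurement film comes from the same sheet as the calibration film, so
  # it carries the same batch offset, which the per-sheet curve absorbs
  px <- film_response_pixel(model, doses) * (1 + attr(cal, "batch_offset"))
  ok <- px >= crv$pixel_span[1] & px <= crv$pixel_span[2]
  est <- dose_from_pixel(crv, px[ok])
  expect_lt(median(abs(est - doses[ok]) / doses[ok]), 0.025)
})

test_that("interpolated doses are unbiased over many seeded replicates", {
  model <- film_response_model("EBT-XD")
  probe <- c(3, 6, 12, 20, 30)
  errs <- vapply(1:200, function(s) {
    pts <- simulate_hd_response(model = model, seed = s)
    crv <- build_hd_curve(pts, order = 4)
    est <- dose_from_pixel(crv, film_response_pixel(model, probe) *
                             (1 + attr(pts, "batch_offset")))
    mean((est - probe) / probe)
  }, numeric(1))
  # mean relative error across replicates ~ 0 within Monte-Carlo error
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)) + 0.005)
})

test_that("order selection by leave-one-out picks a sensible order", {
  expect_true(pick_hd_order(exact_cubic_points()) %in% c(3L, 4L))
  # quartic-shaped response with mild noise should not pick order 3 when
  # order 3 predicts clearly worse
  model <- film_response_model("EBT-XD")
  pts <- simulate_hd_response(model = model, seed = 5)
  crv <- build_hd_curve(pts, order = "auto")
  expect_true(crv$order %in% c(3L, 4L))
})

test_that("curve-set deviations centre on zero and drop sparse doses", {
  pts <- dplyr::bind_rows(
    tibble::tibble(dose_gy = c(2, 5), mean_pixel = c(100, 80),
                   film_model = "EBT-XD", experiment_id = "a"),
    tibble::tibble(dose_gy = c(2, 5), mean_pixel = c(102, 82),
                   film_model = "EBT-XD", experiment_id = "b"),
    tibble::tibble(dose_gy = 2, mean_pixel = 101,
                   film_model = "EBT-XD", experiment_id = "c")
  )
  dev <- curve_set_deviation(pts)
  # dose 5 measured by only two experiments is excluded
  expect_equal(sort(unique(dev$dose_gy)), 2)
  expect_equal(sort(dev$deviation_pct),
               sort(100 * (c(100, 102, 101) / 101 - 1)), tolerance = 1e-12)
  # zero-sum normalisation at each dose
  expect_equal(sum(dev$deviation_pct), 0, tolerance = 1e-12)
  # identical curves deviate by exactly zero
  same <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(id) {
    tibble::tibble(dose_gy = c(1, 4), mean_pixel = c(90, 70),
                   film_model = "EBT-XD", experiment_id = id)
  }))
  expect_true(all(curve_set_deviation(same)$deviation_pct == 0))
  expect_error(curve_set_deviation(pts[pts$experiment_id == "a", ]),
               "two calibration experiments")
})

test_that("curve JSON round trips and tidy/glance summarise the fit", {
  crv <- build_hd_curve(exact_cubic_points(), order = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_hd_curve(crv, path)
  crv2 <- read_hd_curve(path)
  expect_equal(crv2$coefficients, crv$coefficients)
  expect_equal(dose_from_pixel(crv2, 30000), dose_from_pixel(crv, 30000))
  td <- tidy(crv)
  expect_equal(nrow(td), 4)
  expect_equal(glance(crv)$order, 3)
})

test_that("calibration CSV reader validates and returns a tibble", {
  path <- withr::local_tempfile(fileext = ".csv")
  pts <- exact_cubic_points()
  pts$experiment_id <- "exp1"
  write.csv(pts, path, row.names = FALSE)
  back <- read_calibration_csv(path)
  expect_s3_class(back, "tbl_df")
  expect_equal(back$mean_pixel, pts$mean_pixel)
})
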