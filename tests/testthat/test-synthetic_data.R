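test_that("forward film response is monotone and noiseless points exact", {
  for (fm in c("EBT-XD", "RTQA2")) {
    model <- film_response_model(fm)
    d <- seq(0, model$dose_range[2], length.out = 400)
    expect_true(all(diff(film_response_pixel(model, d)) < 0))
  }
  model <- film_response_model("EBT-XD")
  pts <- simulate_hd_response(c(1, 5, 20), model, seed = NULL)
  # seed NULL but sigmas > 0 still draw noise; force noiseless model
  quiet <- film_response_model("EBT-XD", noise_sigma_rel = 0,
                               batch_sigma_rel = 0)
  pts0 <- simulate_hd_response(c(1, 5, 20), quiet, seed = 1)
  expect_equal(pts0$mean_pixel, film_response_pixel(quiet, c(1, 5, 20)))
  expect_error(simulate_hd_response(c(1, 70), model), "range")
})

test_that("replicate curves show the configured batch-offset spread", {
  model <- film_response_model("EBT-XD")
  pts <- simulate_hd_experiments(9, model = model, seed = 123)
  dev <- curve_set_deviation(pts)
  rms <- sqrt(mean(dev$deviation_pct^2))
  # spread compatible with the 2.5% batch scale
  expect_gt(rms, 1.0)
  expect_lt(rms, 4.0)
})

test_that("generators are bit-reproducible for a fixed seed", {
  a <- simulate_hd_response(model = film_response_model(), seed = 7)
  b <- simulate_hd_response(model = film_response_model(), seed = 7)
  expect_identical(a$mean_pixel, b$mean_pixel)
  m <- film_response_model()
  s1 <- render_film(matrix(5, 20, 20), m, seed = 9)
  s2 <- render_film(matrix(5, 20, 20), m, seed = 9)
  expect_identical(s1$pixels, s2$pixels)
  g1 <- simulate_tumour_growth(n_per_group = 3, seed = 4)
  g2 <- simulate_tumour_growth(n_per_group = 3, seed = 4)
  expect_identical(g1, g2)
})

test_that("beam-field generator returns consistent analytic truth", {
  fm <- field_model(field_span_mm = 10, edge_sigma_mm = 1.188,
                    plateau_dose_gy = 30, leakage_fraction = 0.008)
  fld <- simulate_beam_field(fm, grid_mm_per_px = 0.1)
  expect_equal(fld$truth$penumbra_80_20_mm, 1.188 * (qnorm(0.8) - qnorm(0.2)))
  expect_equal(fld$truth$leakage_dose_gy, 0.24)
  # map corners are shielded floor; centre is plateau
  expect_equal(fld$dose[1, 1], 0.24, tolerance = 1e-6)
  centre <- dim(fld$dose) %/% 2
  expect_equal(fld$dose[centre[1], centre[2]], 30, tolerance = 0.01)
  # zero-size field: all-leakage map
  empty <- simulate_beam_field(field_model(field_span_mm = 0,
                                           plateau_dose_gy = 30,
                                           leakage_fraction = 0.008),
                               grid_mm_per_px = 0.5, extent_mm = 5)
  expect_true(all(abs(empty$dose - 0.24) < 1e-12))
})

test_that("noiseless render is the exact forward response", {
  m <- film_response_model("EBT-XD")
  scan <- render_film(matrix(5, 8, 8), m, seed = NULL)
  expect_true(all(scan$pixels == round(film_response_pixel(m, 5))))
})

test_that("phantom exposure honours the analytical model", {
  # mu = 0, no leakage: tumour sites equal, shielded sites ~0
  cfg <- default_sarj_config()
  cfg$depth_dose$mu_eff_per_mm <- 0
  cfg$shield$restraint$thickness_mm <- 1e6 # effectively opaque
  ph0 <- simulate_phantom_exposure(cfg, prescription_gy = 12)
  tum <- dplyr::filter(ph0, grepl("tumour", .data$site))
  expect_true(all(abs(tum$dose_gy - 6) < 1e-9))
  sh <- dplyr::filter(ph0, !grepl("tumour", .data$site))
  expect_true(all(sh$dose_gy < 1e-9))

  # defaults at 30 Gy: shielded sites at the 7.3-HVL transmission level
  ph <- simulate_phantom_exposure(default_sarj_config(), 30)
  totals <- ph |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(total = sum(.data$dose_gy))
  shielded_pct <- 100 * totals$total[totals$site == "body"] / 30
  expect_lt(shielded_pct, 1.3)
  expect_equal(shielded_pct, 100 * transmission(hvl_count(5.1, 0.7)),
               tolerance = 1e-9)

  # per-beam entry-to-midline drop sits in the 5-10% band for the
  # calibrated attenuation
  beam15 <- dplyr::filter(ph, .data$angle_deg == 15)
  entry <- beam15$dose_gy[beam15$site == "tumour_dorsal"]
  mid <- beam15$dose_gy[beam15$site == "tumour_mid"]
  drop_pct <- 100 * (1 - mid / entry)
  expect_gt(drop_pct, 5)
  expect_lt(drop_pct, 10)
  # the two beams mirror through the tumour
  beam195 <- dplyr::filter(ph, .data$angle_deg == 195)
  expect_equal(beam15$dose_gy[beam15$site == "tumour_dorsal"],
               beam195$dose_gy[beam195$site == "tumour_ventral"])
})

test_that("tumour growth generator has correct null and endpoint semantics", {
  # kill 0: treated and control trajectories share the same generating law
  null_model <- growth_model(kill_fraction_per_fraction = 0,
                             regrowth_delay_days = 0)
  rec <- simulate_tumour_growth(null_model, n_per_group = 6, seed = 31)
  truth <- attr(rec, "truth")
  d14 <- dplyr::filter(truth, .data$day == 14)
  t <- rank_sum_exact(d14$true_volume_mm3[d14$group == "control"],
                      d14$true_volume_mm3[d14$group == "irradiated"])
  expect_gt(t$p_value, 0.05)

  # endpoint: event day is the first measurement day at or above threshold
  rec2 <- simulate_tumour_growth(n_per_group = 6, seed = 32)
  per_animal <- split(rec2, rec2$animal_id)
  for (a in per_animal) {
    if (a$event[1]) {
      expect_gte(max(a$volume_mm3), growth_model()$endpoint_volume_mm3)
      expect_equal(a$day[which(a$volume_mm3 >=
                                 growth_model()$endpoint_volume_mm3)[1]],
                   a$event_day[1])
    } else {
      expect_equal(a$event_day[1], 35)
      expect_true(all(a$volume_mm3 < growth_model()$endpoint_volume_mm3))
    }
    # no measurements after the event day
    expect_true(all(a$day <= a$event_day[1]))
  }
})

test_that("a strong treatment effect separates the groups reproducibly", {
  hits <- vapply(1:200, function(s) {
    rec <- simulate_tumour_growth(n_per_group = 4, seed = 1000 + s)
    gs <- growth_summary(rec)
    d14 <- gs[gs$day == 14, ]
    d14$mean_volume_mm3[d14$group == "irradiated"] <
      d14$mean_volume_mm3[d14$group == "control"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
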