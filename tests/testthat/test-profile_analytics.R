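test_that("normalisation maps the plateau to 100% and is idempotent", {
  prof <- dose_profile(seq(-10, 10, by = 0.1), rep(6, 201))
  norm <- normalize_profile(prof, c(-2, 2))
  expect_true(all(norm$dose_pct == 100))
  expect_equal(attr(norm, "plateau_mean"), 6)
  # plateau 6 Gy with a 0.3 Gy tail -> tail at 5%
  x <- seq(-10, 10, by = 0.1)
  two <- dose_profile(x, ifelse(abs(x) <= 4, 6, 0.3))
  n2 <- normalize_profile(two, c(-2, 2))
  expect_equal(n2$dose_pct[abs(x) > 4][1], 5)
  # idempotence on an already-normalised profile
  again <- normalize_profile(n2, c(-2, 2))
  expect_equal(again$dose_pct, n2$dose_pct)
  expect_error(normalize_profile(prof, c(100, 101)), "plateau window")
})

test_that("seeded noisy plateau mean is recovered within 3 SEM", {
  set.seed(17)
  x <- seq(-8, 8, by = 25.4 / 600)
  inside <- abs(x) <= 2
  dose <- 6 * (1 + rnorm(length(x), 0, 0.01))
  prof <- dose_profile(x, dose)
  norm <- normalize_profile(prof, c(-2, 2))
  sem <- 6 * 0.01 / sqrt(sum(inside))
  expect_lt(abs(attr(norm, "plateau_mean") - 6), 3 * sem)
})

test_that("penumbra estimator matches the closed-form erf width", {
  for (sigma in c(0.5, 1.188, 3)) {
    prof <- erf_profile(span = 20, sigma = sigma, extent = 24)
    pw <- penumbra_width(normalize_profile(prof, c(-3, 3)))
    expect_equal(pw$width_mm, rep(erf_width_80_20(sigma), 2),
                 tolerance = 0.02)
  }
  # sigma doubling doubles the width (linearity), within interpolation error
  w1 <- penumbra_width(erf_profile(sigma = 1, span = 16, extent = 18))$width_mm[1]
  w2 <- penumbra_width(erf_profile(sigma = 2, span = 16, extent = 20))$width_mm[1]
  expect_equal(w2 / w1, 2, tolerance = 0.02)
})

test_that("an ideal step edge has penumbra below one sample spacing", {
  step <- 25.4 / 600
  x <- seq(-8, 8, by = step)
  prof <- dose_profile(x, ifelse(abs(x) <= 5, 6, 0))
  pw <- penumbra_width(normalize_profile(prof, c(-2, 2)))
  expect_true(all(pw$width_mm <= step + 1e-12))
})

test_that("50% field edges sit at the nominal field boundary", {
  prof <- erf_profile(span = 10, sigma = 1.188, extent = 14)
  edges <- field_edge_positions(normalize_profile(prof, c(-2, 2)))
  expect_equal(edges$left_mm, -5, tolerance = 0.01)
  expect_equal(edges$right_mm, 5, tolerance = 0.01)
  # step field crossing within one sample
  step <- 0.05
  x <- seq(-8, 8, by = step)
  sp <- dose_profile(x, ifelse(x >= -5 & x <= 5, 6, 0))
  se <- field_edge_positions(normalize_profile(sp, c(-2, 2)))
  expect_lt(abs(se$left_mm - (-5)), step)
  expect_lt(abs(se$right_mm - 5), step)
  flat <- dose_profile(seq(-5, 5, 0.1), rep(6, 101))
  expect_error(field_edge_positions(normalize_profile(flat, c(-1, 1))),
               "never crosses")
})

test_that("margin offset is signed into the tumour side", {
  # 50% edge exactly at the margin -> 0
  at <- erf_profile(span = 10, sigma = 1, extent = 14, margin_mm = -5)
  expect_equal(margin_offset(at), 0, tolerance = 0.01)
  # field shifted 0.5 mm into the tumour side (edge at -4.5, margin -5)
  inside <- erf_profile(span = 10, sigma = 1, extent = 14, centre = 0.5,
                        margin_mm = -5)
  expect_equal(margin_offset(inside), 0.5, tolerance = 0.01)
  # field spilling 1 mm into the shielded side (edge at -6)
  spill <- erf_profile(span = 10, sigma = 1, extent = 14, centre = -1,
                       margin_mm = -5)
  expect_equal(margin_offset(spill), -1, tolerance = 0.01)
  # mirrored geometry: margin on the right edge behaves symmetrically
  right <- erf_profile(span = 10, sigma = 1, extent = 14, centre = -0.5,
                       margin_mm = 5)
  expect_equal(margin_offset(right), 0.5, tolerance = 0.01)
  expect_error(margin_offset(erf_profile(span = 10, sigma = 1)), "margin")
})

test_that("percent dose interpolates against a reference", {
  prof <- dose_profile(c(0, 1, 2), c(0.25, 0.25, 0.25))
  expect_equal(percent_dose_at(prof, 0.5, reference_gy = 5), 5)
  expect_error(percent_dose_at(prof, 0.5, reference_gy = 0), "non-zero")
  expect_error(percent_dose_at(prof, 9, reference_gy = 5), "outside")
})

test_that("shielded-site percent dose respects the physics bound", {
  cfg <- default_sarj_config()
  cfg$scatter_fraction <- 0.005
  ph <- simulate_phantom_exposure(cfg, prescription_gy = 30)
  shielded <- dplyr::filter(ph, .data$site %in% c("head", "body", "rear")) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(total = sum(.data$dose_gy))
  pct <- 100 * shielded$total / 30
  roof_only <- 100 * (transmission(7) + 0.005)
  expect_true(all(pct <= roof_only + 1e-9))
})

test_that("site uniformity reports SEM% and max deviation separately", {
  equal <- site_uniformity(rep(5, 5))
  expect_equal(equal$sem_percent, 0)
  expect_equal(equal$max_abs_dev_percent, 0)
  s <- site_uniformity(c(5.0, 5.2, 4.9, 5.1, 4.8))
  expect_equal(s$mean_gy, 5)
  expect_equal(s$max_abs_dev_percent, 4)
  expect_equal(s$sem_percent, 100 * sd(c(5, 5.2, 4.9, 5.1, 4.8)) / sqrt(5) / 5)
})

test_that("pairwise summation of anticorrelated beams reduces deviation", {
  set.seed(23)
  jitter <- rnorm(5, 0, 0.10)
  beam_a <- 6 * (1 + jitter)
  beam_b <- 6 * (1 - jitter) # anticorrelated setup errors
  totals <- beam_a + beam_b
  dev_single <- site_uniformity(beam_a)$max_abs_dev_percent
  dev_total <- site_uniformity(totals)$max_abs_dev_percent
  expect_lt(dev_total, dev_single)
})

test_that("profile CSV round trips with its margin comment", {
  prof <- erf_profile(span = 10, sigma = 1, margin_mm = -5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- read_profile_csv(path)
  expect_equal(back$dose_gy, prof$dose_gy, tolerance = 1e-9)
  expect_equal(attr(back, "margin_mm"), -5)
})

test_that("profile_metrics assembles the full metric set", {
  prof <- erf_profile(span = 10, sigma = 1.188, extent = 14, margin_mm = -5)
  m <- profile_metrics(prof, plateau_window = c(-2, 2))
  expect_equal(m$penumbra_80_20_left_mm, erf_width_80_20(1.188),
               tolerance = 0.02)
  expect_equal(m$edge_50_left_mm, -5, tolerance = 0.01)
  expect_equal(m$margin_offset_mm, 0, tolerance = 0.01)
  # analytic flatness over the central 80% of a 10 mm field with
  # sigma = 1.188 mm edges: the core reaches the penumbra shoulder, so the
  # max deviation is 100 - 100 * field_fraction(4 mm) relative to plateau
  frac4 <- pnorm((4 + 5) / 1.188) - pnorm((4 - 5) / 1.188)
  plateau <- mean(pnorm((seq(-2, 2, 25.4 / 600) + 5) / 1.188) -
                    pnorm((seq(-2, 2, 25.4 / 600) - 5) / 1.188))
  expect_equal(m$flatness_percent, 100 * (1 - frac4 / plateau),
               tolerance = 0.02)
})
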