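# Fixtures built in code: exact polynomial calibration sets, erf-edge
# profiles, and small oracle implementations used across test files.

# Calibration points whose dose is an EXACT cubic in pixel value:
# with u = (pixel - 38000) / 18000 in [-1, 1],
#   dose = 30 - 28 u - 2 u^3  (strictly decreasing in pixel, 0..60 Gy).
exact_cubic_dose <- function(pixel) {
  u <- (pixel - 38000) / 18000
  30 - 28 * u - 2 * u^3
}

exact_cubic_points <- function(n = 12, film_model = "EBT-XD") {
  px <- seq(20000, 56000, length.out = n)
  tibble::tibble(
    dose_gy = exact_cubic_dose(px),
    mean_pixel = px,
    film_model = film_model
  )
}

# Analytic erf-edge profile: a field of width `span` centred at `centre`
# with edge spread `sigma`, sampled at `step` mm.
erf_profile <- function(span = 10, sigma = 1.188, step = 25.4 / 600,
                        plateau = 6, extent = span / 2 + 8, centre = 0,
                        leakage = 0, margin_mm = NULL) {
  x <- seq(centre - extent, centre + extent, by = step)
  frac <- pnorm((x - (centre - span / 2)) / sigma) -
    pnorm((x - (centre + span / 2)) / sigma)
  dose_profile(x, plateau * (leakage + (1 - leakage) * frac),
               margin_mm = margin_mm)
}

# Closed-form 80-20% width of an erf edge.
erf_width_80_20 <- function(sigma) (qnorm(0.8) - qnorm(0.2)) * sigma

# Wrap a bare pixel matrix as a film_scan (red channel, 16-bit scale).
new_scan_for_test <- function(pixels, dpi = 600) {
  sarjdose:::new_film_scan(pixels, dpi = dpi, channels = "red-only")
}

# Independent Mann-Whitney U oracle: direct pair counting with half-credit
# for ties (U of x = #{x_i > y_j} + 0.5 #{x_i == y_j}).
u_pair_count <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Independent exact two-sided p oracle by enumeration over labelings,
# measuring extremeness as distance of U from its null centre.
p_enumeration <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  centre <- n1 * length(y) / 2
  u_obs <- u_pair_count(x, y)
  labelings <- combn(length(pooled), n1)
  u_all <- apply(labelings, 2, function(idx) {
    u_pair_count(pooled[idx], pooled[-idx])
  })
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
}
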