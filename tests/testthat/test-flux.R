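test_that("fit_slope matches hand OLS and handles degenerate series", {
  # collinear points: 0.5 ppm per 15 min = 2 ppm/h
  s <- fit_slope(c(0, 15, 30), c(2.0, 2.5, 3.0))
  expect_equal(s$slope_ppm_h, 2.0)
  expect_equal(s$r2, 1)
  # sign symmetry
  s_dn <- fit_slope(c(0, 15, 30), c(3.0, 2.5, 2.0))
  expect_equal(s_dn$slope_ppm_h, -2.0)
  # constant series: zero slope, r2 reported as 1 by convention
  s0 <- fit_slope(c(0, 15, 30), c(2, 2, 2))
  expect_equal(s0$slope_ppm_h, 0)
  expect_equal(s0$r2, 1)
  # two points: endpoint slope, r2 = 1
  s2 <- fit_slope(c(0, 30), c(2, 3))
  expect_equal(s2$slope_ppm_h, 2)
  expect_equal(s2$r2, 1)
  # noisy 3-point: agree with lm()
  set.seed(4)
  tt <- c(0, 15, 30); cc <- 2 + 0.03 * tt + rnorm(3, 0, 0.1)
  ref <- lm(cc ~ I(tt / 60))
  s3 <- fit_slope(tt, cc)
  expect_equal(s3$slope_ppm_h, unname(coef(ref)[2]))
  expect_equal(s3$r2, summary(ref)$r.squared)
  expect_error(fit_slope(0, 2), "at least 2")
  expect_error(fit_slope(c(0, 0, 30), c(1, 2, 3)), "duplicate")
})

test_that("compute_flux evaluates the chamber equation and is linear", {
  expect_equal(compute_flux(0, 1, 25), 0)
  expect_equal(compute_flux(1, 1, 0), 0.717)
  expect_equal(compute_flux(1, 1, 27), 0.717 * 273 / 300)
  # linear in slope and H; antisymmetric in slope
  expect_equal(compute_flux(3, 2, 10), 6 * compute_flux(1, 1, 10))
  expect_equal(compute_flux(-1.5, 1, 10), -compute_flux(1.5, 1, 10))
  # temperature correction strictly decreasing in T
  temps <- seq(-10, 40, by = 5)
  fl <- compute_flux(1, 1, temps)
  expect_true(all(diff(fl) < 0))
  expect_error(compute_flux(1, 0, 25), "positive")
  expect_error(compute_flux(1, 1, -280), "absolute zero")
})

test_that("cumulative_emission equals the trapezoid rule on hand cases", {
  d0 <- as.Date("2023-07-01")
  fl <- tibble::tibble(plot_id = "P1", date = c(d0, d0 + 10), flux = c(1, 1))
  out <- cumulative_emission(fl)
  expect_equal(out$cumulative_S, 240)       # (1+1)/2 * 10 d * 24 h
  expect_equal(out$n_samplings, 2L)
  expect_equal(out$mean_flux_paper_literal, 120)
  expect_equal(out$mean_flux_arithmetic, 1)
  # all-zero season
  flz <- tibble::tibble(plot_id = "P1", date = d0 + c(0, 3, 9), flux = 0)
  expect_equal(cumulative_emission(flz)$cumulative_S, 0)
  # flux linear in time -> trapezoid is exact for the linear interpolant
  days <- c(0, 4, 7, 15, 30)
  fll <- tibble::tibble(plot_id = "P1", date = d0 + days, flux = 2 + 0.5 * days)
  S <- cumulative_emission(fll)$cumulative_S
  exact <- (2 * 30 + 0.5 * 30^2 / 2) * 24
  expect_equal(S, exact)
  expect_error(
    cumulative_emission(tibble::tibble(plot_id = "P1", date = c(d0, d0), flux = 1:2)),
    "duplicate"
  )
})

test_that("cumulative_emission matches an independent brute-force sum on random seasons", {
  set.seed(11)
  d0 <- as.Date("2022-06-15")
  for (i in 1:100) {
    k <- sample(3:12, 1)
    days <- sort(sample(0:120, k))
    flux <- rnorm(k, 5, 4)
    out <- cumulative_emission(tibble::tibble(plot_id = "P", date = d0 + days, flux = flux))
    # naive loop oracle
    S <- 0
    for (j in seq_len(k - 1)) S <- S + (flux[j] + flux[j + 1]) / 2 * (days[j + 1] - days[j]) * 24
    expect_equal(out$cumulative_S, S, tolerance = 1e-9)
  }
})

test_that("mean_flux supports windows and both averaging definitions", {
  d0 <- as.Date("2023-07-01")
  fl <- tibble::tibble(plot_id = "P1", date = d0 + c(0, 10, 50), flux = c(1, 3, 8))
  expect_equal(mean_flux(fl)$mean_flux, 4)
  w <- mean_flux(fl, window = c(d0, d0 + 20))
  expect_equal(w$mean_flux, 2)
  # trapezoid over days 0-10 of fluxes (1, 3) is 480 mg m^-2, over 2 records
  lit <- mean_flux(fl, window = c(d0, d0 + 10), method = "paper_literal")
  expect_equal(lit$mean_flux, 480 / 2)
  expect_error(mean_flux(fl, window = c(d0 + 60, d0 + 70)), "no flux records")
})

test_that("percent_reduction handles halving, identity and negative-flux cases", {
  expect_equal(percent_reduction(10, 5), 50)
  expect_equal(percent_reduction(10, 10), 0)
  expect_equal(percent_reduction(10, -1), 110)
  expect_error(percent_reduction(0, 5), "zero reference")
})

test_that("chamber_fluxes converts a vial-level field sheet to per-closure fluxes", {
  d0 <- as.Date("2023-07-01")
  fs <- tibble::tibble(
    plot_id = rep(c("A", "B"), each = 3),
    treatment = rep(c("60N", "60N+Fe"), each = 3),
    date = d0,
    t_min = rep(c(0, 15, 30), 2),
    conc_ppm = c(2, 2.5, 3, 2, 2, 2),
    chamber_height_m = 1,
    temp_c = 27
  )
  out <- chamber_fluxes(fs)
  expect_equal(nrow(out), 2)
  expect_equal(out$flux[out$plot_id == "A"], 0.717 * 2 * 273 / 300)
  expect_equal(out$flux[out$plot_id == "B"], 0)
  # mg m^-3 ingestion divides the density back out
  out2 <- chamber_fluxes(dplyr::mutate(fs, conc_ppm = conc_ppm * 0.717),
                         conc_unit = "mg_m3")
  expect_equal(out2$flux, out$flux)
  # qc flag, not drop
  noisy <- dplyr::mutate(fs, conc_ppm = c(2, 3.2, 2.4, 2, 2, 2))
  out3 <- chamber_fluxes(noisy, qc_r2 = 0.9)
  expect_equal(nrow(out3), 2)
  expect_false(out3$qc_pass[out3$plot_id == "A"])
})

test_that("compare_treatments reproduces textbook one- and two-way ANOVA", {
  # two groups containing identical values: no between-group variance
  d <- tibble::tibble(treatment = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  a <- compare_treatments(d, "y")
  expect_equal(a$oneway$f_statistic, 0)
  expect_equal(a$oneway$p_value, 1)
  # clear separation flagged by Tukey
  d2 <- tibble::tibble(treatment = rep(c("a", "b"), each = 4), y = rep(c(0, 10), each = 4))
  a2 <- compare_treatments(d2, "y")
  expect_lt(a2$oneway$p_value, 0.001)
  expect_true(all(tidy(a2)$p_adj < 0.001))
  # balanced 2x2 purely additive design: Fe main effect, zero interaction
  d3 <- tidyr::expand_grid(n_rate = c(60, 80), fe = c(FALSE, TRUE), rep = 1:3) |>
    dplyr::mutate(treatment = paste0(n_rate, ifelse(fe, "Fe", "")),
                  y = 10 + 2 * (n_rate == 80) - 4 * fe + 0)
  # add tiny orthogonal jitter so residual df is nonzero but balanced
  d3$y <- d3$y + rep(c(-0.01, 0, 0.01), times = 4)
  a3 <- compare_treatments(d3, "y", n_rate = "n_rate", fe = "fe")
  tw <- a3$twoway
  expect_lt(tw$p_value[tw$term == "Fe"], 1e-6)
  expect_lt(tw$f_statistic[tw$term == "N_rate:Fe"], 1e-6)
  # group with one replicate is named in the error
  bad <- dplyr::bind_rows(d2, tibble::tibble(treatment = "c", y = 1))
  expect_error(compare_treatments(bad, "y"), "c")
})
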