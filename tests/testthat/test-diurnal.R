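test_that("local solar time offsets by longitude and wraps the day", {
  expect_equal(local_solar_time(12, 30), 14)
  expect_equal(local_solar_time(12, 0), 12)
  expect_equal(local_solar_time(1, -45), 22)
  expect_error(local_solar_time(12, 190), "lon")
})

test_that("sub-daily rates difference time-adjacent valid samples", {
  times <- c(7, 7.25, 7.5)
  r <- subdaily_rates(c(290, 290.5, 291), times = times)
  expect_equal(r$rate, c(2, 2))
  expect_equal(r$mid_lst, c(290.25, 290.75))
  # QC gap: increment spans the flagged sample
  r2 <- subdaily_rates(c(290, 999, 291), qc = c(TRUE, FALSE, TRUE),
                       times = times)
  expect_equal(r2$rate, 2)
  expect_equal(r2$mid_lst, 290.5)
  # constant series
  expect_equal(subdaily_rates(rep(300, 3), times = times)$rate, c(0, 0))
  # fewer than two valid samples -> empty
  expect_equal(nrow(subdaily_rates(c(290, 291), qc = c(TRUE, FALSE),
                                   times = c(7, 7.25))), 0)
  # gaps longer than the cap yield no increment
  r3 <- subdaily_rates(c(290, 295), times = c(7, 10), max_gap = 2)
  expect_equal(nrow(r3), 0)
})

test_that("daily median rate handles empty and exact-ramp cases", {
  expect_equal(daily_median_rate(c(1, 2, 3)), 2)
  expect_true(is.na(daily_median_rate(numeric(0))))
  # exact ramp: every increment equals the slope
  inc <- subdaily_rates(290 + 1.7 * seq(0, 3.75, 0.25),
                        times = seq(7, 10.75, 0.25))
  expect_equal(daily_median_rate(inc$rate), 1.7)
})

test_that("inserting a QC-invalid sample never changes the daily median", {
  set.seed(5)
  times <- seq(7, 10.5, 0.5)
  for (i in 1:20) {
    lst <- 290 + cumsum(runif(length(times), 0, 0.8))
    qc <- rep(TRUE, length(times))
    base <- daily_median_rate(subdaily_rates(lst, qc, times)$rate)
    # splice an invalid sample between two existing ones
    j <- sample(length(times) - 1, 1)
    times2 <- sort(c(times, times[j] + 0.25))
    k <- which(times2 == times[j] + 0.25)[1]
    lst2 <- append(lst, 999, after = k - 1)
    qc2 <- append(qc, FALSE, after = k - 1)
    expect_equal(daily_median_rate(subdaily_rates(lst2, qc2, times2)$rate),
                 base)
  }
})

test_that("a noise-free ramp recovers its slope exactly despite QC gaps", {
  set.seed(31)
  for (gap in c(0, 0.3, 0.5)) {
    cube <- ramp_cube(r = 2.4, n_days = 8, gap_prob = gap)
    rm <- rate_map(cube, analysis_config(min_valid_days = 1))
    got <- rm$rate_daily[!is.na(rm$rate_daily)]
    expect_true(length(got) > 0)
    expect_equal(got, rep(2.4, length(got)), tolerance = 1e-12)
    expect_equal(rm$rate_annual[1], 2.4, tolerance = 1e-12)
  }
})

test_that("diurnal range is the 13:30 minus 06:00 difference with QC", {
  cube <- ramp_cube(r = 2.5, n_days = 2)           # DTR = 6 h * slope
  dtr <- diurnal_range(cube)
  expect_equal(dtr[1, ], c(15, 15))
  cube$qc[1, 1, which(cube$times == 6)] <- FALSE   # morning sample flagged
  expect_true(is.na(diurnal_range(cube)[1, 1]))
  iso <- ramp_cube(r = 0, n_days = 1)              # isothermal day
  expect_equal(diurnal_range(iso)[1, 1], 0)
})

test_that("window means average valid samples then days", {
  cube <- ramp_cube(r = 2, n_days = 2)
  idx <- which(cube$times >= 8 & cube$times <= 8.5)
  cube$lst[1, , idx] <- rep(c(300, 302, 304), each = 2)
  expect_equal(window_mean_lst(cube, c(8, 8.5))[1], 302)
  cube$qc[1, , idx[2:3]] <- FALSE                  # single valid sample left
  expect_equal(window_mean_lst(cube, c(8, 8.5))[1], 300)
  cube$qc[1, , idx] <- FALSE                       # none valid
  expect_true(is.na(window_mean_lst(cube, c(8, 8.5))[1]))
})

test_that("rate and DTR are perfectly correlated on piecewise-linear days", {
  # DTR = 6 * rate + 0 by the diurnal shape, so spatial correlation is 1
  cfg <- scene_config(nx = 6, ny = 5, n_days = 6, seed = 8,
                      cloud_gap_prob = 0, noise_sd_lst = 0.02)
  sc <- generate_scene(cfg)
  rm <- rate_map(sc$cube, analysis_config(min_valid_days = 1))
  rho <- rate_dtr_correlation(rm$rate_daily, rm$dtr_daily)
  expect_true(all(rho > 0.99))
  # degenerate: constant rates across pixels
  rd <- matrix(1, 4, 2); dd <- matrix(rnorm(8), 4, 2)
  r2 <- rate_dtr_correlation(rd, dd)
  expect_true(all(is.na(r2)))
  expect_true(all(attr(r2, "degenerate")))
  # exactly proportional fields give correlation 1
  x <- matrix(rnorm(12), 6, 2)
  expect_equal(rate_dtr_correlation(x, 6 * x + 3), c(1, 1),
               ignore_attr = TRUE)
})
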