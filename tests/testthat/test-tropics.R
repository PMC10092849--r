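test_that("significant linear trends are removed exactly, others untouched", {
  y <- 280 + 0.1 * (1:19)                          # exact trend, zero noise
  out <- detrend_if_significant(y)
  expect_true(attr(out, "detrended"))
  expect_equal(as.numeric(out), rep(mean(y), 19), tolerance = 1e-10)
  const <- rep(290, 12)                            # undefined trend test
  out2 <- detrend_if_significant(const)
  expect_false(attr(out2, "detrended"))
  expect_equal(as.numeric(out2), const)
  expect_error(detrend_if_significant(rnorm(5)), "at least 10")
})

test_that("trend screening keeps white noise unchanged about 95% of the time", {
  set.seed(23)
  kept <- vapply(1:200, function(i) {
    !attr(detrend_if_significant(rnorm(19)), "detrended")
  }, TRUE)
  expect_gt(mean(kept), 0.90)
  expect_lt(mean(kept), 0.99)
})

test_that("detrending is idempotent", {
  set.seed(7)
  for (i in 1:20) {
    y <- rnorm(19) + (i %% 3) * 0.2 * (1:19)
    once <- detrend_if_significant(y)
    twice <- detrend_if_significant(as.numeric(once))
    expect_equal(as.numeric(twice), as.numeric(once), tolerance = 1e-8)
  }
})

test_that("the interannual fit recovers an exact linear system", {
  set.seed(3)
  ndvi <- runif(19, 0.2, 0.6)
  p <- runif(19, 300, 900)
  rs <- runif(19, 200, 280)
  lst <- 2 - 5 * ndvi + 0.001 * p + 0.01 * rs
  fit <- fit_lst_drivers(ndvi, lst, p, rs)
  expect_equal(unname(coef(fit)), c(-5, 0.001, 0.01), tolerance = 1e-8)
  expect_null(fit_lst_drivers(rep(0.4, 19), lst, p, rs))   # NDVI constant
  expect_null(fit_lst_drivers(ndvi[1:8], lst[1:8], p[1:8], rs[1:8]))
})

test_that("delta LST scales the NDVI coefficient by 1% of mean NDVI", {
  expect_equal(delta_lst(-10, 0.5), -0.05)
  expect_equal(delta_lst(-10, 0), 0)
  expect_equal(delta_lst(0, 0.5), 0)
})

test_that("precipitation coverage tables partition pixels and sum to 100", {
  cls <- factor(c(rep("cooling", 4), rep("neutral", 3), "warming"),
                levels = c("cooling", "neutral", "warming"))
  precip <- c(rep(200, 4), rep(800, 4))
  tb <- coverage_by_precip(cls, precip, breaks = c(0, 500, 1000))
  expect_equal(nrow(tb), 2)
  expect_equal(sum(tb$n), 8)                       # every pixel counted once
  expect_equal(tb$cooling_pct[1], 100)             # all-cooling bin
  expect_equal(rowSums(tb[, c("warming_pct", "neutral_pct", "cooling_pct")]),
               c(100, 100), ignore_attr = TRUE)
})

test_that("the dryland reduction follows its closed-form identity", {
  # two-valued map: humid -0.1 K, dryland -0.05 K, fraction f
  # reduction_mean = 100 * f * (1 - r), r = dry/humid ratio
  set.seed(14)
  for (i in 1:10) {
    n <- 500
    f <- runif(1, 0.1, 0.6)
    r <- runif(1, 0.2, 0.9)
    dry <- seq_len(n) <= round(f * n)
    f_real <- mean(dry)
    delta <- ifelse(dry, -0.1 * r, -0.1)
    red <- dryland_cooling_reduction(delta, dry)
    expect_equal(red$reduction_mean, 100 * f_real * (1 - r), tolerance = 1e-9)
  }
  # no drylands -> zero by convention
  expect_equal(dryland_cooling_reduction(rnorm(10), rep(FALSE, 10))$reduction_mean, 0)
  # identical distributions -> no reduction, non-significant
  red2 <- dryland_cooling_reduction(rep(-0.1, 40), rep(c(TRUE, FALSE), 20))
  expect_equal(red2$reduction_mean, 0)
  expect_true(is.na(red2$ttest_p) || red2$ttest_p > 0.05)
})

test_that("scaling every NDVI coefficient leaves the reduction unchanged", {
  set.seed(9)
  delta <- -runif(200, 0.02, 0.2)
  dry <- runif(200) < 0.3
  r1 <- dryland_cooling_reduction(delta, dry)
  r3 <- dryland_cooling_reduction(3 * delta, dry)
  expect_equal(r3$reduction_mean, r1$reduction_mean, tolerance = 1e-10)
  expect_equal(r3$reduction_median, r1$reduction_median, tolerance = 1e-10)
  expect_equal(r3$mean_delta_all, 3 * r1$mean_delta_all, tolerance = 1e-12)
})

test_that("regional breakdowns scale with dryland coverage", {
  delta <- c(ifelse(seq_len(100) <= 10, -0.05, -0.1),   # region A: 10% dry
             ifelse(seq_len(100) <= 60, -0.05, -0.1))   # region B: 60% dry
  region <- rep(c("A", "B"), each = 100)
  dry <- delta == -0.05
  tb <- regional_breakdown(delta, region, dry)
  expect_gt(tb$reduction_mean[tb$region == "B"],
            tb$reduction_mean[tb$region == "A"])
  # single region equals the global summary
  one <- regional_breakdown(delta, rep("all", 200), dry)
  glob <- dryland_cooling_reduction(delta, dry)
  expect_equal(one$reduction_mean, glob$reduction_mean)
})

test_that("the tropical chain recovers planted greening sensitivities", {
  sc <- cached_scene("tropics",
                     scene_config(nx = 25, ny = 20, n_days = 2, seed = 77))
  a3 <- assess_tropics(sc, analysis_config())
  # planted Delta-LST: -0.05 K (dryland), -0.10 K (humid) per 1% greening
  dry <- dryland_mask(sc$fields$precip_annual) == "dryland"
  veg <- vegetated_mask(landcover = sc$fields$landcover, mode = "igbp_bare")
  expect_equal(mean(a3$delta[dry & veg], na.rm = TRUE), -0.05, tolerance = 0.02)
  expect_equal(mean(a3$delta[!dry & veg], na.rm = TRUE), -0.10, tolerance = 0.02)
  ratio <- a3$reduction$mean_delta_dryland / a3$reduction$mean_delta_humid
  expect_equal(ratio, 0.5, tolerance = 0.1)
  expect_lt(a3$reduction$ttest_p, 0.05)
  # estimated sensitivities track the planted per-pixel truth
  ok <- !is.na(a3$delta)
  expect_gt(cor(a3$delta[ok], sc$truth$delta_lst_true[ok]), 0.8)
})
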