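test_that("bins tile the moisture/radiation plane deterministically", {
  cfg <- analysis_config()
  # floor arithmetic on the 0.005 x 2.5 tiling
  b <- build_bins(c(0.1000, 0.1049, 0.1060), c(700, 700, 700), cfg)
  ids <- vapply(unclass(b), `[[`, "", "bin_id")
  expect_equal(length(b), 2)                       # 0.1000 and 0.1049 share a bin
  expect_true("20:280" %in% ids)                   # floor(0.1/0.005), floor(700/2.5)
  expect_true("21:280" %in% ids)                   # floor(0.106/0.005) = 21
  b2 <- build_bins(c(0.1, 0.1), c(700.0, 702.6), cfg)
  ids2 <- vapply(unclass(b2), `[[`, "", "bin_id")
  expect_setequal(ids2, c("20:280", "20:281"))     # floor(702.6/2.5) = 281
})

test_that("every bin member lies within the half-width tolerances", {
  set.seed(4)
  cfg <- analysis_config()
  theta <- runif(400, 0.05, 0.35)
  rs <- runif(400, 200, 300)
  bins <- build_bins(theta, rs, cfg)
  all_px <- unlist(lapply(unclass(bins), `[[`, "pixels"))
  expect_equal(sort(all_px), 1:400)                # each pixel in exactly one bin
  for (b in unclass(bins)) {
    expect_true(all(abs(theta[b$pixels] - b$theta_center) <=
                      cfg$theta_half_width + 1e-12))
    expect_true(all(abs(rs[b$pixels] - b$rs_center) <=
                      cfg$rs_half_width + 1e-12))
  }
  expect_warning(build_bins(theta, rs, cfg, pixels = integer(0)), "no pixels")
})

test_that("the within-bin FVC fit is exact on collinear data", {
  fit <- fit_fvc_effect(c(0.2, 0.4, 0.6), c(2.0, 1.5, 1.0), min_n = 3)
  expect_equal(fit$beta, -2.5, tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 3), tolerance = 1e-12)
  expect_error(fit_fvc_effect(rep(0.3, 25), rnorm(25)), "degenerate regressor")
  expect_error(fit_fvc_effect(runif(5), rnorm(5)), "insufficient pixels")
})

test_that("effects classify by sign and significance, reported per 0.1 FVC", {
  est <- structure(list(beta = -0.3, p = 0.01), class = "vt_effect_fit")
  expect_equal(as.character(classify_effect(est)$class), "cooling")
  est$beta <- 0.2; est$p <- 0.20
  expect_equal(as.character(classify_effect(est)$class), "neutral")
  est$beta <- -2.5; est$p <- 0.001
  cl <- classify_effect(est)
  expect_equal(cl$beta_per_step, -0.25)            # exactly 0.1 x per-unit beta
})

test_that("area fractions sum to 100 and respect weights", {
  cls <- factor(c("cooling", "cooling", "neutral", "warming"),
                levels = c("cooling", "neutral", "warming"))
  fr <- area_fractions(cls)
  expect_equal(unname(fr), c(50, 25, 25))
  expect_equal(sum(fr), 100)
  expect_equal(unname(area_fractions(factor(rep("cooling", 3),
                                            levels = levels(cls)))),
               c(100, 0, 0))
  frw <- area_fractions(cls, weights = c(1, 1, 2, 0))
  expect_equal(unname(frw), c(50, 50, 0))
})

test_that("gradient summaries are monotone along a planted aridity gradient", {
  sc <- exact_scene()
  a1 <- assess_fvc_effect(sc, small_cfg())
  tb <- gradient_summary(a1$beta_per_step, a1$class,
                         sc$fields$precip_annual, breaks = "deciles")
  bm <- tb$beta_mean[!is.na(tb$beta_mean)]
  expect_true(all(diff(bm) <= 1e-9))               # cooling strengthens with rain
  # single bin reduces to the grand mean
  one <- gradient_summary(a1$beta_per_step, a1$class,
                          sc$fields$precip_annual, breaks = c(0, 2000))
  expect_equal(one$beta_mean, mean(a1$beta_per_step, na.rm = TRUE))
  # land-cover binning with one class gives one row
  lc <- gradient_summary(a1$beta_per_step, a1$class,
                         factor(rep("grassland", length(a1$class))))
  expect_equal(nrow(lc), 1)
})

test_that("the seasonal split partitions days by the pixel's FVC median", {
  lab <- seasonal_split(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(as.character(lab), c("low_fvc", "low_fvc", "high_fvc", "high_fvc"))
  expect_error(seasonal_split(rep(0.3, 10)), "constant FVC")
  # a day exactly at the median joins the high-FVC half
  lab2 <- seasonal_split(c(0.1, 0.2, 0.3))
  expect_equal(as.character(lab2)[2], "high_fvc")
})

test_that("the controlled seasonal fit recovers exact linear structure", {
  set.seed(2)
  n <- 50
  fvc <- runif(n); theta <- runif(n, 0.1, 0.3); rs <- runif(n, 200, 300)
  rate <- 1 + 2 * fvc - 3 * theta + 0.05 * rs
  fit <- fit_fvc_effect_controlled(fvc, rate, theta, rs)
  expect_equal(fit$beta, 2, tolerance = 1e-9)
  expect_equal(unname(coef(fit)), c(1, 2, -3, 0.05), tolerance = 1e-9)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-9)
  expect_false(fit$collinear)
})

test_that("seasonal percent differences match the reporting convention", {
  expect_equal(env_percent_difference(0.084, 0.100), -16)
  expect_equal(env_percent_difference(5, 5), 0)
  expect_equal(env_percent_difference(1.12 * 240, 240), 12, tolerance = 1e-12)
  expect_warning(out <- env_percent_difference(1, 0), "zero")
  expect_true(is.na(out))
})

test_that("seasonal assessment separates effects and environments by season", {
  sc <- cached_scene("seasonal",
                     scene_config(nx = 12, ny = 45, n_days = 40, seed = 21))
  ss <- assess_seasonal(sc, analysis_config())
  # dryland low-vegetation season is drier and sunnier than the year
  ed <- ss$env_diff
  expect_lt(ed$percent_diff[ed$season == "low_fvc" & ed$variable == "theta"], -5)
  expect_gt(ed$percent_diff[ed$season == "low_fvc" & ed$variable == "rs"], 5)
  expect_gt(ed$percent_diff[ed$season == "low_fvc" & ed$variable == "vpd"], 1)
  expect_lt(abs(ed$percent_diff[ed$season == "high_fvc" & ed$variable == "theta"] +
                  ed$percent_diff[ed$season == "low_fvc" & ed$variable == "theta"]),
            6)
  expect_true(all(c("low_fvc", "high_fvc") %in% ss$bins$season))
  expect_true(all(is.finite(ss$bins$delta_beta)))
})

test_that("interannual DTR regression recovers a planted slope", {
  set.seed(12)
  hits <- 0
  for (i in 1:20) {
    fvc <- runif(16, 0.2, 0.6)
    dtr <- 10 - 2 * fvc + rnorm(16, 0, 0.1)
    fit <- interannual_fvc_regression(dtr, fvc)
    if (fit$ci[1] <= -2 && -2 <= fit$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 17)                             # ~95% CI coverage
  expect_null(interannual_fvc_regression(rnorm(16), rep(0.4, 16)))
  expect_null(interannual_fvc_regression(rnorm(5), runif(5)))
})
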