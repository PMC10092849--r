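# Spatial conditioning: bins of near-identical long-term soil moisture and
# shortwave radiation, within-bin OLS of the morning warming rate on FVC,
# effect classification, seasonal controlled regressions, and the
# interannual DTR robustness variant.

#' Conditioning bins over soil moisture and shortwave radiation
#'
#' Deterministic tiling of the (theta, R_S) plane into cells of width twice
#' the configured half-widths (default 0.005 m3 m-3 by 2.5 W m-2), anchored
#' at zero. Every member pixel lies within the half-width tolerances of its
#' bin centre, and every pixel belongs to exactly one bin.
#'
#' @param theta_mean long-term mean soil moisture per pixel (m3 m-3).
#' @param rs_mean long-term mean shortwave radiation per pixel (W m-2).
#' @param cfg an [analysis_config()].
#' @param pixels optional integer indices restricting the pixels considered
#'   (e.g. the vegetated mask); defaults to all.
#' @return list of class `vt_bins`; each element has `bin_id`,
#'   `theta_center`, `rs_center`, `pixels` (indices into the input vectors)
#'   and `n`.
#' @export
build_bins <- function(theta_mean, rs_mean, cfg = analysis_config(),
                       pixels = NULL) {
  if (is.null(pixels)) pixels <- seq_along(theta_mean)
  pixels <- pixels[is.finite(theta_mean[pixels]) & is.finite(rs_mean[pixels])]
  if (length(pixels) == 0) {
    warning("no pixels available for binning")
    return(structure(list(), class = "vt_bins"))
  }
  wt <- 2 * cfg$theta_half_width
  wr <- 2 * cfg$rs_half_width
  ti <- floor(theta_mean[pixels] / wt)
  ri <- floor(rs_mean[pixels] / wr)
  key <- paste(ti, ri, sep = ":")
  groups <- split(seq_along(pixels), key)
  bins <- lapply(seq_along(groups), function(i) {
    idx <- groups[[i]]
    list(bin_id = names(groups)[i],
         theta_center = (ti[idx[1]] + 0.5) * wt,
         rs_center = (ri[idx[1]] + 0.5) * wr,
         pixels = pixels[idx],
         n = length(idx))
  })
  structure(bins, class = "vt_bins")
}

#' @export
print.vt_bins <- function(x, ...) {
  n <- vapply(unclass(x), `[[`, integer(1), "n")
  cat(sprintf("<vt_bins> %d bins over %d pixels (bin sizes %s)\n",
              length(x), sum(n),
              if (length(n)) paste0(min(n), "-", max(n)) else "-"))
  invisible(x)
}

# Shared OLS core for the within-bin fits. `x` is a data.frame of
# regressors (first column is the effect of interest), `y` the response.
.bin_ols <- function(x, y, term, alpha, min_n) {
  ok <- stats::complete.cases(x) & !is.na(y)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n < min_n) stop("insufficient pixels (n = ", n, ", need ", min_n, ")")
  if (stats::var(x[[1]]) == 0) stop("degenerate regressor: zero variance in ", term)
  dat <- cbind(y = y, x)
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 1 - alpha)
  kappa_x <- if (ncol(x) > 1) kappa(stats::model.matrix(fit)) else 1
  est <- list(beta0 = unname(stats::coef(fit)[1]),
              beta = unname(stats::coef(fit)[term]),
              coefficients = stats::coef(fit)[-1],
              se = unname(sm[term, 2]),
              p = unname(sm[term, 4]),
              ci = unname(ci[term, ]),
              n = n,
              term = term,
              residuals = unname(stats::residuals(fit)),
              collinear = is.finite(kappa_x) && kappa_x > 1e8,
              alpha = alpha)
  class(est) <- "vt_effect_fit"
  est
}

#' Within-bin regression of the warming rate on FVC
#'
#' Ordinary least squares of the annual-mean morning d(LST)/dt on
#' annual-mean FVC across the pixels of one conditioning bin. The slope is
#' the net biophysical effect of vegetation cover on the warming rate for
#' that water/energy regime: significantly negative = cooling,
#' significantly positive = warming.
#'
#' @param fvc_mean annual-mean FVC of the bin's pixels.
#' @param rate_annual annual-mean morning warming rate (K h-1).
#' @param alpha two-sided significance level (also sets the CI level).
#' @param min_n minimum pixels (default 20: 10 per fitted coefficient).
#' @return object of class `vt_effect_fit` with elements `beta0`, `beta`
#'   (K h-1 per unit FVC), `se`, `p`, `ci`, `n`, `residuals`.
#' @export
fit_fvc_effect <- function(fvc_mean, rate_annual, alpha = 0.05, min_n = 20) {
  .bin_ols(data.frame(fvc = fvc_mean), rate_annual, "fvc", alpha, min_n)
}

#' Seasonal controlled regression of the warming rate on FVC
#'
#' As [fit_fvc_effect()] but on seasonal means with seasonal-mean soil
#' moisture and shortwave radiation as additional regressors, controlling
#' for direct environmental effects on LST that do not involve vegetation.
#'
#' @param fvc,rate,theta,rs seasonal means across the bin's pixels.
#' @param alpha significance level.
#' @param min_n minimum pixels (default 40: 10 per fitted coefficient).
#' @return `vt_effect_fit`; the `collinear` flag marks ill-conditioned fits.
#' @export
fit_fvc_effect_controlled <- function(fvc, rate, theta, rs,
                                      alpha = 0.05, min_n = 40) {
  .bin_ols(data.frame(fvc = fvc, theta = theta, rs = rs), rate,
           "fvc", alpha, min_n)
}

#' Classify a fitted FVC effect
#'
#' Significantly negative slopes are cooling, significantly positive are
#' warming, everything else neutral. Also reports the effect per 0.1
#' absolute FVC increase (`beta * fvc_report_step`).
#'
#' @param est a `vt_effect_fit`.
#' @param alpha significance level.
#' @param fvc_report_step FVC step for the reported effect size.
#' @return list with `class` (factor cooling/neutral/warming), `beta`,
#'   `beta_per_step`, `p`.
#' @export
classify_effect <- function(est, alpha = 0.05, fvc_report_step = 0.1) {
  cls <- if (!is.na(est$p) && est$p < alpha) {
    if (est$beta < 0) "cooling" else if (est$beta > 0) "warming" else "neutral"
  } else "neutral"
  list(class = factor(cls, levels = c("cooling", "neutral", "warming")),
       beta = est$beta,
       beta_per_step = est$beta * fvc_report_step,
       p = est$p)
}

#' Areal fractions of cooling / neutral / warming effects
#'
#' @param classes factor of per-pixel classes (levels cooling, neutral,
#'   warming); `NA` pixels (unclassified) are excluded.
#' @param weights optional per-pixel area weights.
#' @return named numeric: percent cooling, neutral, warming (sums to 100).
#' @export
area_fractions <- function(classes, weights = NULL) {
  classes <- factor(classes, levels = c("cooling", "neutral", "warming"))
  if (is.null(weights)) weights <- rep(1, length(classes))
  ok <- !is.na(classes)
  w <- tapply(weights[ok], classes[ok], sum, default = 0)
  c(100 * w / sum(w))
}

#' Effect summary along an environmental gradient
#'
#' Bins the per-pixel effect sizes by total annual precipitation (numeric
#' breaks or deciles) or by land-cover class and tabulates per-bin mean and
#' median effect (per 0.1 FVC) and class fractions.
#'
#' @param beta_per_step per-pixel effect size (K h-1 per 0.1 FVC).
#' @param classes per-pixel class factor.
#' @param by numeric precipitation (with `breaks`) or a factor of codes.
#' @param breaks numeric break points, or `"deciles"`.
#' @return data.frame, one row per bin.
#' @export
gradient_summary <- function(beta_per_step, classes, by, breaks = "deciles") {
  if (is.numeric(by)) {
    if (identical(breaks, "deciles"))
      breaks <- stats::quantile(by, probs = seq(0, 1, 0.1), na.rm = TRUE)
    grp <- cut(by, breaks = unique(breaks), include.lowest = TRUE)
  } else grp <- factor(by)
  lv <- levels(grp)
  rows <- lapply(lv, function(g) {
    i <- which(grp == g)
    if (!length(i))
      return(data.frame(bin = g, n = 0L, beta_mean = NA_real_,
                        beta_median = NA_real_, cooling_pct = NA_real_,
                        neutral_pct = NA_real_, warming_pct = NA_real_))
    fr <- area_fractions(classes[i])
    data.frame(bin = g, n = length(i),
               beta_mean = mean(beta_per_step[i], na.rm = TRUE),
               beta_median = stats::median(beta_per_step[i], na.rm = TRUE),
               cooling_pct = fr[["cooling"]], neutral_pct = fr[["neutral"]],
               warming_pct = fr[["warming"]])
  })
  do.call(rbind, rows)
}

#' Split a pixel's year into low- and high-vegetation halves
#'
#' Day labels by the pixel's own FVC median: days strictly below the median
#' are the low-vegetation season; ties go to the high-vegetation season.
#'
#' @param fvc_series daily FVC values over the year.
#' @return factor of day labels (`low_fvc`, `high_fvc`).
#' @export
seasonal_split <- function(fvc_series) {
  if (length(unique(fvc_series[!is.na(fvc_series)])) < 2)
    stop("constant FVC series: pixel excluded from seasonal analysis")
  med <- stats::median(fvc_series, na.rm = TRUE)
  factor(ifelse(fvc_series < med, "low_fvc", "high_fvc"),
         levels = c("low_fvc", "high_fvc"))
}

#' Percent difference of a seasonal mean from the annual mean
#'
#' @param seasonal seasonal mean of an environmental variable.
#' @param annual annual mean of the same variable; must be non-zero.
#' @return percent difference `100 * (seasonal - annual) / annual`;
#'   `NA` with a warning when the annual mean is zero.
#' @export
env_percent_difference <- function(seasonal, annual) {
  out <- 100 * (seasonal - annual) / annual
  if (any(annual == 0, na.rm = TRUE)) {
    warning("annual mean of zero: percent difference undefined")
    out[annual == 0] <- NA_real_
  }
  out
}

#' Interannual regression of annual DTR on annual FVC
#'
#' Per-pixel robustness variant: does the spatial FVC effect also hold in
#' time? OLS of a pixel's annual diurnal temperature range on its annual
#' FVC, optionally controlling for annual precipitation.
#'
#' @param dtr_annual annual DTR values (K), one per year.
#' @param fvc_annual annual FVC values.
#' @param precip_annual optional annual precipitation control (mm yr-1).
#' @param alpha significance level.
#' @param min_years minimum complete years (default 8).
#' @return `vt_effect_fit`, or `NULL` when there are too few years or the
#'   FVC series is degenerate (missing value, not an error).
#' @export
interannual_fvc_regression <- function(dtr_annual, fvc_annual,
                                       precip_annual = NULL,
                                       alpha = 0.05, min_years = 8) {
  x <- data.frame(fvc = fvc_annual)
  if (!is.null(precip_annual)) x$p <- precip_annual
  ok <- stats::complete.cases(x) & !is.na(dtr_annual)
  if (sum(ok) < min_years) return(NULL)
  if (stats::var(fvc_annual[ok]) == 0) return(NULL)
  .bin_ols(x[ok, , drop = FALSE], dtr_annual[ok], "fvc", alpha,
           min_n = min_years)
}
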