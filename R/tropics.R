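# Tropical interannual attribution: per-pixel regression of annual LST on
# NDVI with precipitation and radiation controls, the LST change per 1%
# greening, and the dryland reduction of the net vegetal cooling effect.

#' Remove a linear trend when it is statistically significant
#'
#' Fits a linear trend against year and, when its two-sided p-value is
#' below `alpha`, returns the residuals recentred on the series mean;
#' otherwise the series is returned unchanged. A constant series has an
#' undefined trend test and is treated as trend-free. Applying the
#' operation twice equals applying it once.
#'
#' @param series annual values.
#' @param alpha significance level for the trend test.
#' @param min_years minimum series length.
#' @return the (possibly detrended) series with attribute `detrended`.
#' @export
detrend_if_significant <- function(series, alpha = 0.05, min_years = 10) {
  if (sum(!is.na(series)) < min_years)
    stop("need at least ", min_years, " years")
  yr <- seq_along(series)
  out <- series
  flag <- FALSE
  if (stats::var(series, na.rm = TRUE) > 0) {
    fit <- stats::lm(series ~ yr)
    p <- summary(fit)$coefficients["yr", 4]
    if (is.finite(p) && p < alpha) {
      out[!is.na(series)] <- unname(stats::residuals(fit)) +
        mean(series, na.rm = TRUE)
      flag <- TRUE
    }
  }
  attr(out, "detrended") <- flag
  out
}

#' Interannual regression of annual LST on NDVI, precipitation, radiation
#'
#' Per-pixel multiple OLS of (trend-screened) annual mean LST on
#' (trend-screened) annual NDVI with annual precipitation and shortwave
#' radiation as controls. Significant linear trends are removed from LST
#' and NDVI only, to avoid confounding by long-term co-trends.
#'
#' @param ndvi,lst,p,rs annual series of equal length (one pixel).
#' @param alpha significance level (trend screen and NDVI p-value/CI).
#' @param min_years minimum complete years.
#' @return list of class `vt_interannual_fit` with `beta_ndvi` (K per NDVI
#'   unit), `beta_p` (K per mm yr-1), `beta_rs` (K per W m-2), `p_ndvi`,
#'   `ci_ndvi`, `n_years` and `detrended` flags; `NULL` (missing fit) when
#'   preconditions fail (too few years, degenerate regressor, rank
#'   deficiency).
#' @export
fit_lst_drivers <- function(ndvi, lst, p, rs, alpha = 0.05, min_years = 10) {
  ok <- stats::complete.cases(ndvi, lst, p, rs)
  if (sum(ok) < min_years) return(NULL)
  ndvi <- ndvi[ok]; lst <- lst[ok]; p <- p[ok]; rs <- rs[ok]
  if (stats::var(ndvi) == 0 || stats::var(p) == 0 || stats::var(rs) == 0)
    return(NULL)
  lst_d <- detrend_if_significant(lst, alpha, min_years)
  ndvi_d <- detrend_if_significant(ndvi, alpha, min_years)
  fit <- stats::lm(y ~ ndvi + p + rs,
                   data = data.frame(y = as.numeric(lst_d),
                                     ndvi = as.numeric(ndvi_d), p = p, rs = rs))
  if (fit$rank < 4) return(NULL)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, "ndvi", level = 1 - alpha)
  structure(list(beta_ndvi = unname(stats::coef(fit)["ndvi"]),
                 beta_p = unname(stats::coef(fit)["p"]),
                 beta_rs = unname(stats::coef(fit)["rs"]),
                 p_ndvi = unname(sm["ndvi", 4]),
                 ci_ndvi = unname(ci[1, ]),
                 n_years = length(lst),
                 detrended = c(lst = attr(lst_d, "detrended"),
                               ndvi = attr(ndvi_d, "detrended")),
                 alpha = alpha),
            class = "vt_interannual_fit")
}

#' @export
print.vt_interannual_fit <- function(x, ...) {
  cat(sprintf("<vt_interannual_fit> beta_NDVI %.3f K/NDVI (p = %.3g), beta_P %.4g, beta_RS %.4g; %d years%s\n",
              x$beta_ndvi, x$p_ndvi, x$beta_p, x$beta_rs, x$n_years,
              if (any(x$detrended)) paste0(" (detrended: ",
                paste(names(x$detrended)[x$detrended], collapse = ", "), ")") else ""))
  invisible(x)
}

#' LST change per 1% relative NDVI increase
#'
#' The greening sensitivity: the NDVI coefficient scaled by 1% of the
#' pixel's mean annual NDVI, i.e. how much annual LST would change if the
#' pixel's mean NDVI rose by 1% of itself.
#'
#' @param fit a `vt_interannual_fit` (or a numeric NDVI coefficient).
#' @param mean_ndvi pixel mean annual NDVI over the record.
#' @return LST change (K).
#' @export
delta_lst <- function(fit, mean_ndvi) {
  beta <- if (inherits(fit, "vt_interannual_fit")) fit$beta_ndvi else fit
  beta * 0.01 * mean_ndvi
}

#' Effect-class coverage by precipitation bin
#'
#' Percent of pixels with significant cooling, significant warming and
#' neutral interannual NDVI effects, within bins of mean annual
#' precipitation. Rows sum to 100.
#'
#' @param classes per-pixel factor (cooling / neutral / warming).
#' @param precip mean annual precipitation per pixel (mm yr-1).
#' @param breaks numeric precipitation break points.
#' @return data.frame with one row per non-empty precipitation bin.
#' @export
coverage_by_precip <- function(classes, precip,
                               breaks = seq(0, 3000, by = 250)) {
  grp <- cut(precip, breaks = unique(breaks), include.lowest = TRUE)
  rows <- lapply(levels(grp), function(g) {
    i <- which(grp == g & !is.na(classes))
    if (!length(i)) return(NULL)
    fr <- area_fractions(classes[i])
    data.frame(precip_bin = g, n = length(i),
               warming_pct = fr[["warming"]], neutral_pct = fr[["neutral"]],
               cooling_pct = fr[["cooling"]])
  })
  do.call(rbind, rows)
}

#' Dryland reduction of the net tropical cooling effect
#'
#' Compares the spatial distribution of the per-1%-greening LST change
#' with and without drylands included. The reduction is how much weaker
#' the all-tropics mean (median) cooling is than the humid-only mean
#' (median), in percent; a Welch t-test compares the two distributions.
#'
#' @param delta per-pixel LST change per 1% NDVI increase (K).
#' @param dryland logical (or `dryland`/`humid` factor) per pixel.
#' @param weights optional area weights (means only; medians are unweighted).
#' @param ttest which two distributions the Welch t-test compares:
#'   `"all_vs_humid"` (with vs without drylands included) or the
#'   independent-group `"dryland_vs_humid"` variant.
#' @return list of class `vt_reduction`: `mean_delta_all`,
#'   `mean_delta_humid`, `mean_delta_dryland`, `reduction_mean`,
#'   `reduction_median` (%), `ttest_p`, `dryland_area_fraction` (%).
#' @export
dryland_cooling_reduction <- function(delta, dryland, weights = NULL,
                                      ttest = c("all_vs_humid",
                                                "dryland_vs_humid")) {
  ttest <- match.arg(ttest)
  if (is.factor(dryland) || is.character(dryland))
    dryland <- as.character(dryland) == "dryland"
  ok <- !is.na(delta) & !is.na(dryland)
  delta <- delta[ok]; dryland <- dryland[ok]
  if (is.null(weights)) weights <- rep(1, length(delta)) else weights <- weights[ok]
  wmean <- function(x, w) sum(x * w) / sum(w)
  m_all <- wmean(delta, weights)
  frac_dry <- 100 * sum(weights[dryland]) / sum(weights)
  if (!any(dryland) || !any(!dryland)) {
    return(structure(list(mean_delta_all = m_all,
                          mean_delta_humid = if (any(!dryland)) m_all else NA_real_,
                          mean_delta_dryland = if (any(dryland)) m_all else NA_real_,
                          reduction_mean = 0, reduction_median = 0,
                          ttest_p = NA_real_,
                          dryland_area_fraction = frac_dry),
                     class = "vt_reduction"))
  }
  m_humid <- wmean(delta[!dryland], weights[!dryland])
  m_dry <- wmean(delta[dryland], weights[dryland])
  md_all <- stats::median(delta)
  md_humid <- stats::median(delta[!dryland])
  if (m_humid == 0 || md_humid == 0)
    warning("humid mean/median of zero: reduction undefined")
  red_mean <- if (m_humid != 0) 100 * (m_humid - m_all) / m_humid else NA_real_
  red_median <- if (md_humid != 0) 100 * (md_humid - md_all) / md_humid else NA_real_
  g1 <- if (ttest == "all_vs_humid") delta else delta[dryland]
  g2 <- delta[!dryland]
  tt <- if (length(g1) >= 2 && length(g2) >= 2 &&
            stats::sd(g1) > 0 && stats::sd(g2) > 0)
    stats::t.test(g1, g2, var.equal = FALSE)$p.value else NA_real_
  structure(list(mean_delta_all = m_all, mean_delta_humid = m_humid,
                 mean_delta_dryland = m_dry,
                 reduction_mean = red_mean, reduction_median = red_median,
                 ttest_p = tt, dryland_area_fraction = frac_dry),
            class = "vt_reduction")
}

#' @export
print.vt_reduction <- function(x, ...) {
  cat(sprintf("<vt_reduction> Delta-LST mean: all %.4g K, humid %.4g K, dryland %.4g K\n",
              x$mean_delta_all, x$mean_delta_humid, x$mean_delta_dryland))
  cat(sprintf("  dryland reduction of net cooling: %.1f%% (mean), %.1f%% (median); drylands %.1f%% of area; t-test p = %.3g\n",
              x$reduction_mean, x$reduction_median, x$dryland_area_fraction,
              x$ttest_p))
  invisible(x)
}

#' Regional breakdown of the dryland cooling reduction
#'
#' @param delta per-pixel LST change per 1% NDVI increase (K).
#' @param region factor of region labels partitioning the domain.
#' @param dryland logical dryland flag per pixel.
#' @return data.frame, one row per region, with the reduction statistics
#'   and dryland area percentage.
#' @export
regional_breakdown <- function(delta, region, dryland) {
  region <- factor(region)
  rows <- lapply(levels(region), function(rg) {
    i <- which(region == rg)
    r <- dryland_cooling_reduction(delta[i], dryland[i])
    data.frame(region = rg, n = length(i),
               reduction_mean = r$reduction_mean,
               reduction_median = r$reduction_median,
               dryland_area_pct = r$dryland_area_fraction,
               ttest_p = r$ttest_p)
  })
  do.call(rbind, rows)
}
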