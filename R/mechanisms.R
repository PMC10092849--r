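# Mechanism diagnostics: energy-dissipation efficiency from the
# d(LST)/dt-versus-LST slope, surface-albedo sensitivity to FVC within
# conditioning bins, shortwave forcing of an albedo change, and bootstrap
# dryland-vs-humid contrasts.

# Unitless normalization applied to the negated d(LST)/dt-vs-LST slope,
# after Bateni & Entekhabi's force-restore scaling (their Eq. 12).
DISSIPATION_NORMALIZATION <- 32.5

#' Energy-dissipation efficiency per pixel
#'
#' Fits, per pixel, the linear dependence of the 15-min finite-difference
#' warming rate on the concurrent (midpoint) LST, pooling all valid
#' increments. A surface that sheds absorbed energy efficiently slows its
#' warming as it heats, so the slope is negative; the efficiency is the
#' negated slope scaled by the unitless normalization factor 32.5.
#'
#' @param increments data.frame/data.table with columns `pixel`, `rate`
#'   (K h-1) and `mid_lst` (K), e.g. from a full-day increment extraction;
#'   a `vt_cube` may be passed directly.
#' @param min_increments minimum increments per pixel.
#' @param min_lst_range minimum LST span (K) of a pixel's increments.
#' @param max_gap maximum hours an increment may span (cube input).
#' @param n_pixels total pixel count (defaults to the largest pixel index
#'   seen; pass explicitly when trailing pixels may have no increments).
#' @return list of class `vt_dissipation` with per-pixel `beta_eff`
#'   (unitless), `slope_raw` (h-1), `n_increments` and `reason` for missing
#'   pixels.
#' @export
dissipation_efficiency <- function(increments, min_increments = 10,
                                   min_lst_range = 1, max_gap = 2,
                                   n_pixels = NULL) {
  if (inherits(increments, "vt_cube")) {
    if (is.null(n_pixels)) n_pixels <- dim(increments$lst)[1]
    increments <- cube_rates(increments, window = NULL, max_gap = max_gap)
  }
  dt <- data.table::as.data.table(increments)
  if (!all(c("pixel", "rate", "mid_lst") %in% names(dt)))
    stop("increments must have columns pixel, rate, mid_lst")
  if (nrow(dt) == 0) stop("no increments supplied")
  st <- dt[, list(n = .N,
                  range = max(mid_lst) - min(mid_lst),
                  slope = {
                    vx <- stats::var(mid_lst)
                    if (.N >= 2 && vx > 0)
                      stats::cov(mid_lst, rate) / vx else NA_real_
                  }),
           by = "pixel"]
  npix <- if (is.null(n_pixels)) max(st$pixel) else n_pixels
  slope <- rep(NA_real_, npix)
  n_inc <- integer(npix)
  reason <- rep(NA_character_, npix)
  n_inc[st$pixel] <- st$n
  ok <- st$n >= min_increments & st$range > min_lst_range & !is.na(st$slope)
  slope[st$pixel[ok]] <- st$slope[ok]
  reason[st$pixel[!ok]] <- ifelse(st$n[!ok] < min_increments,
                                  "insufficient increments",
                                  "insufficient LST range")
  missing_px <- setdiff(seq_len(npix), st$pixel)
  reason[missing_px] <- "insufficient increments"
  structure(list(beta_eff = -slope * DISSIPATION_NORMALIZATION,
                 slope_raw = slope, n_increments = n_inc, reason = reason),
            class = "vt_dissipation")
}

#' @export
print.vt_dissipation <- function(x, ...) {
  ok <- !is.na(x$beta_eff)
  cat(sprintf("<vt_dissipation> %d/%d pixels fitted; median efficiency %.3f\n",
              sum(ok), length(ok),
              if (any(ok)) stats::median(x$beta_eff[ok]) else NA_real_))
  invisible(x)
}

#' Within-bin sensitivity of surface albedo to FVC
#'
#' OLS of long-term mean surface albedo on mean FVC across the pixels of a
#' conditioning bin, identical in form to the warming-rate fit. A more
#' negative slope means vegetation gains darken the surface more strongly.
#'
#' @param fvc_mean,albedo_mean values for the bin's pixels.
#' @param alpha significance level.
#' @param min_n minimum pixels.
#' @return `vt_effect_fit`; `beta` is albedo change per unit FVC (multiply
#'   by 0.1 for the per-0.1-FVC reporting convention).
#' @export
albedo_sensitivity <- function(fvc_mean, albedo_mean, alpha = 0.05,
                               min_n = 20) {
  .bin_ols(data.frame(fvc = fvc_mean), albedo_mean, "fvc", alpha, min_n)
}

#' Shortwave forcing of an albedo change
#'
#' The change in absorbed shortwave radiation implied by an albedo change
#' under the local mean downwelling flux: a darkening (negative
#' `delta_albedo`) increases absorption.
#'
#' @param delta_albedo albedo change (fraction).
#' @param rs_mean mean downwelling shortwave radiation (W m-2), > 0.
#' @return forcing in W m-2 (positive = more absorbed energy).
#' @export
radiative_forcing <- function(delta_albedo, rs_mean) {
  if (any(rs_mean <= 0, na.rm = TRUE)) stop("rs_mean must be > 0")
  -delta_albedo * rs_mean
}

#' Dryland-vs-humid contrast with bootstrap confidence interval
#'
#' Group means of a per-pixel (or per-bin) statistic for drylands and
#' humid surfaces, their difference, and a percentile bootstrap 95% CI of
#' the difference from resampling values within each group. The contrast
#' is significant when the CI excludes zero.
#'
#' @param values numeric statistic per unit.
#' @param group factor with levels `dryland`, `humid`.
#' @param reps bootstrap resamples.
#' @param conf confidence level.
#' @return list of class `vt_contrast` with `means`, `difference`
#'   (dryland - humid), `ci`, `significant`, `reps`, `n`.
#' @export
group_contrast <- function(values, group, reps = 1000, conf = 0.95) {
  group <- factor(group, levels = c("dryland", "humid"))
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- group[ok]
  nd <- sum(group == "dryland"); nh <- sum(group == "humid")
  if (nd < 5 || nh < 5)
    stop("each group needs at least 5 values (dryland ", nd, ", humid ", nh, ")")
  vd <- values[group == "dryland"]; vh <- values[group == "humid"]
  boot <- replicate(reps,
    mean(vd[sample.int(nd, nd, replace = TRUE)]) -
      mean(vh[sample.int(nh, nh, replace = TRUE)]))
  ci <- unname(stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  structure(list(means = c(dryland = mean(vd), humid = mean(vh)),
                 difference = mean(vd) - mean(vh),
                 ci = ci,
                 significant = ci[1] > 0 || ci[2] < 0,
                 reps = reps, n = c(dryland = nd, humid = nh)),
            class = "vt_contrast")
}

#' @export
print.vt_contrast <- function(x, ...) {
  cat(sprintf("<vt_contrast> dryland %.4g vs humid %.4g; diff %.4g [%.4g, %.4g]%s (%d reps)\n",
              x$means[1], x$means[2], x$difference, x$ci[1], x$ci[2],
              if (x$significant) " *" else "", x$reps))
  invisible(x)
}
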