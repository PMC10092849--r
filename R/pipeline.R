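# Assessment chains: scene in, classified effect maps and summaries out.
# These wire the module operations together in the order a satellite
# analysis would run them.

#' Assessment I: net FVC effect on the morning warming rate
#'
#' Full chain on a scene: compute the daily median morning d(LST)/dt and
#' its annual mean, drop non-vegetated pixels (mean FVC of zero), bin the
#' remaining pixels by long-term soil moisture and shortwave radiation,
#' regress the annual rate on annual-mean FVC within each adequately sized
#' bin, classify each bin's effect, and aggregate area fractions.
#'
#' @param scene a `vt_scene` (or a list with `cube`, `fields`, `daily`).
#' @param cfg an [analysis_config()].
#' @param rates optionally a precomputed [rate_map()] for the scene's cube.
#' @return list of class `vt_assessment1`: `rates` (`vt_rate_map`),
#'   `bins` (per-bin fit table), `class` (per-pixel factor),
#'   `beta_per_step` (per-pixel effect per 0.1 FVC, inherited from the
#'   bin), `fractions` (percent cooling/neutral/warming),
#'   `n_unclassified` (vegetated pixels in inadequate or degenerate bins).
#' @export
assess_fvc_effect <- function(scene, cfg = analysis_config(), rates = NULL) {
  if (is.null(rates)) rates <- rate_map(scene$cube, cfg)
  fields <- scene$fields
  npix <- nrow(fields)
  fvc_annual <- if (!is.null(scene$daily)) rowMeans(scene$daily$fvc)
                else fields$fvc_mean
  veg <- vegetated_mask(fvc_mean = fields$fvc_mean, mode = "fvc_zero")
  usable <- which(veg & !is.na(rates$rate_annual))
  bins <- build_bins(fields$theta_mean, fields$rs_mean, cfg, pixels = usable)
  min_n <- 2 * cfg$min_pixels_per_regressor
  cls <- factor(rep(NA_character_, npix),
                levels = c("cooling", "neutral", "warming"))
  beta_step <- rep(NA_real_, npix)
  rows <- lapply(unclass(bins), function(b) {
    row <- data.frame(bin_id = b$bin_id, theta_center = b$theta_center,
                      rs_center = b$rs_center, n = b$n, beta = NA_real_,
                      beta_per_step = NA_real_, p = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_,
                      class = NA_character_, flag = NA_character_)
    fit <- tryCatch(fit_fvc_effect(fvc_annual[b$pixels],
                                   rates$rate_annual[b$pixels],
                                   alpha = cfg$alpha_level, min_n = min_n),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) { row$flag <- fit; return(list(row = row, fit = NULL, b = b)) }
    cl <- classify_effect(fit, cfg$alpha_level, cfg$fvc_report_step)
    row$beta <- fit$beta; row$beta_per_step <- cl$beta_per_step
    row$p <- fit$p; row$ci_lo <- fit$ci[1]; row$ci_hi <- fit$ci[2]
    row$class <- as.character(cl$class)
    list(row = row, fit = fit, b = b, class = cl$class)
  })
  for (r in rows) {
    if (is.null(r$fit)) next
    cls[r$b$pixels] <- r$class
    beta_step[r$b$pixels] <- r$row$beta_per_step
  }
  bin_table <- do.call(rbind, lapply(rows, `[[`, "row"))
  structure(list(rates = rates, bins = bin_table, class = cls,
                 beta_per_step = beta_step,
                 fractions = area_fractions(cls),
                 n_unclassified = sum(veg & is.na(cls)),
                 fits = lapply(rows, `[[`, "fit"),
                 bin_pixels = lapply(rows, function(r) r$b$pixels),
                 config = cfg),
            class = "vt_assessment1")
}

#' @export
print.vt_assessment1 <- function(x, ...) {
  fr <- x$fractions
  cat("<vt_assessment1> net FVC effect on d(LST)/dt\n")
  cat(sprintf("  %d bins (%d fitted); classified pixels: %d\n",
              nrow(x$bins), sum(!is.na(x$bins$beta)), sum(!is.na(x$class))))
  cat(sprintf("  cooling %.1f%% | neutral %.1f%% | warming %.1f%% of classified area\n",
              fr[["cooling"]], fr[["neutral"]], fr[["warming"]]))
  invisible(x)
}

#' Assessment II seasonal chain: controlled seasonal FVC effects
#'
#' Splits each pixel's year into low- and high-vegetation halves by its
#' own FVC median, forms seasonal means of the daily median rate, FVC,
#' soil moisture and shortwave radiation, and refits the within-bin FVC
#' effect per season with the seasonal environmental means as controls.
#' Also reports the dryland percent difference of each environmental
#' variable between season and full year.
#'
#' @param scene a `vt_scene` with day-level environmental series.
#' @param cfg an [analysis_config()].
#' @param overall optionally a precomputed [assess_fvc_effect()] result
#'   (for the seasonal-minus-overall effect differences).
#' @return list of class `vt_seasonal`: `bins` (per-bin, per-season fit
#'   table incl. `delta_beta` against the overall fit), `env_diff`
#'   (dryland percent differences of theta, R_S, VPD, FVC per season),
#'   `fractions` (per-season class fractions).
#' @export
assess_seasonal <- function(scene, cfg = analysis_config(), overall = NULL) {
  if (is.null(overall)) overall <- assess_fvc_effect(scene, cfg)
  rates <- overall$rates
  fields <- scene$fields
  npix <- nrow(fields)
  nd <- ncol(scene$daily$fvc)

  split_lab <- matrix(NA_character_, npix, nd)
  excluded <- logical(npix)
  for (px in seq_len(npix)) {
    lab <- tryCatch(seasonal_split(scene$daily$fvc[px, ]),
                    error = function(e) NULL)
    if (is.null(lab)) { excluded[px] <- TRUE; next }
    split_lab[px, ] <- as.character(lab)
  }

  smean <- function(mat, px, season)
    mean(mat[px, which(split_lab[px, ] == season)], na.rm = TRUE)
  seasons <- c("low_fvc", "high_fvc")
  seas_stats <- lapply(seasons, function(se) {
    list(rate = vapply(seq_len(npix), function(px)
           if (excluded[px]) NA_real_ else smean(rates$rate_daily, px, se), 0),
         fvc = vapply(seq_len(npix), function(px)
           if (excluded[px]) NA_real_ else smean(scene$daily$fvc, px, se), 0),
         theta = vapply(seq_len(npix), function(px)
           if (excluded[px]) NA_real_ else smean(scene$daily$theta, px, se), 0),
         rs = vapply(seq_len(npix), function(px)
           if (excluded[px]) NA_real_ else smean(scene$daily$rs, px, se), 0),
         vpd = vapply(seq_len(npix), function(px)
           if (excluded[px]) NA_real_ else smean(scene$daily$vpd, px, se), 0))
  })
  names(seas_stats) <- seasons

  usable <- which(!excluded & !is.na(rates$rate_annual) &
                    vegetated_mask(fvc_mean = fields$fvc_mean, mode = "fvc_zero"))
  bins <- build_bins(fields$theta_mean, fields$rs_mean, cfg, pixels = usable)
  min_n <- 4 * cfg$min_pixels_per_regressor
  overall_beta <- stats::setNames(overall$bins$beta, overall$bins$bin_id)
  rows <- list()
  cls_by_season <- list()
  for (se in seasons) {
    st <- seas_stats[[se]]
    cls <- factor(rep(NA_character_, npix),
                  levels = c("cooling", "neutral", "warming"))
    for (b in unclass(bins)) {
      fit <- tryCatch(fit_fvc_effect_controlled(
        st$fvc[b$pixels], st$rate[b$pixels], st$theta[b$pixels],
        st$rs[b$pixels], alpha = cfg$alpha_level, min_n = min_n),
        error = function(e) NULL)
      if (is.null(fit)) next
      cl <- classify_effect(fit, cfg$alpha_level, cfg$fvc_report_step)
      cls[b$pixels] <- cl$class
      rows[[length(rows) + 1L]] <- data.frame(
        season = se, bin_id = b$bin_id, n = fit$n, beta = fit$beta,
        beta_per_step = cl$beta_per_step, p = fit$p,
        delta_beta = fit$beta - unname(overall_beta[b$bin_id]),
        collinear = fit$collinear)
    }
    cls_by_season[[se]] <- cls
  }

  dry <- dryland_mask(fields$precip_annual, cfg$dryland_threshold) == "dryland"
  annual <- list(fvc = rowMeans(scene$daily$fvc),
                 theta = rowMeans(scene$daily$theta),
                 rs = rowMeans(scene$daily$rs),
                 vpd = rowMeans(scene$daily$vpd))
  env_diff <- do.call(rbind, lapply(seasons, function(se) {
    st <- seas_stats[[se]]
    vals <- vapply(c("fvc", "theta", "rs", "vpd"), function(v)
      env_percent_difference(mean(st[[v]][dry], na.rm = TRUE),
                             mean(annual[[v]][dry], na.rm = TRUE)), 0)
    data.frame(season = se, variable = names(vals), percent_diff = vals,
               row.names = NULL)
  }))

  structure(list(bins = do.call(rbind, rows), env_diff = env_diff,
                 class_by_season = cls_by_season,
                 fractions = lapply(cls_by_season, area_fractions),
                 seasonal_means = seas_stats, excluded = excluded),
            class = "vt_seasonal")
}

#' Assessment II mechanism chain: dissipation efficiency and albedo
#'
#' Per-pixel energy-dissipation efficiency from all diurnal rate
#' increments, per-bin albedo sensitivity to FVC, and bootstrap
#' dryland-vs-humid contrasts of both.
#'
#' @param scene a `vt_scene`.
#' @param cfg an [analysis_config()].
#' @return list of class `vt_mechanisms`: `dissipation`
#'   (`vt_dissipation`), `albedo_bins` (per-bin sensitivity table),
#'   `contrast_eff` and `contrast_albedo` (`vt_contrast`).
#' @export
assess_mechanisms <- function(scene, cfg = analysis_config()) {
  fields <- scene$fields
  diss <- dissipation_efficiency(scene$cube, max_gap = cfg$max_gap_hours)
  veg <- vegetated_mask(fvc_mean = fields$fvc_mean, mode = "fvc_zero")
  usable <- which(veg)
  bins <- build_bins(fields$theta_mean, fields$rs_mean, cfg, pixels = usable)
  min_n <- 2 * cfg$min_pixels_per_regressor
  rows <- lapply(unclass(bins), function(b) {
    fit <- tryCatch(albedo_sensitivity(fields$fvc_mean[b$pixels],
                                       fields$albedo_mean[b$pixels],
                                       alpha = cfg$alpha_level, min_n = min_n),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    dry_bin <- stats::median(fields$precip_annual[b$pixels]) < cfg$dryland_threshold
    data.frame(bin_id = b$bin_id, theta_center = b$theta_center,
               rs_center = b$rs_center, n = b$n, beta = fit$beta,
               beta_per_step = fit$beta * cfg$fvc_report_step, p = fit$p,
               dryland = dry_bin)
  })
  albedo_bins <- do.call(rbind, rows)
  dry_px <- dryland_mask(fields$precip_annual, cfg$dryland_threshold)
  contrast_eff <- tryCatch(
    group_contrast(diss$beta_eff[veg], dry_px[veg], reps = cfg$bootstrap_reps),
    error = function(e) NULL)
  contrast_alb <- if (!is.null(albedo_bins) && nrow(albedo_bins) >= 10)
    tryCatch(group_contrast(albedo_bins$beta,
                            ifelse(albedo_bins$dryland, "dryland", "humid"),
                            reps = cfg$bootstrap_reps),
             error = function(e) NULL) else NULL
  structure(list(dissipation = diss, albedo_bins = albedo_bins,
                 contrast_eff = contrast_eff, contrast_albedo = contrast_alb),
            class = "vt_mechanisms")
}

#' Assessment III chain: tropical interannual attribution
#'
#' Per-pixel interannual regression of annual LST on NDVI (with
#' precipitation and radiation controls and trend screening), the LST
#' change per 1% greening, significance classes, coverage by
#' precipitation, and the dryland reduction of net cooling.
#'
#' @param scene a `vt_scene` with an annual panel.
#' @param cfg an [analysis_config()].
#' @param mask_mode bare-soil removal rule (see [vegetated_mask()]).
#' @return list of class `vt_assessment3`: `fits` (per pixel, `NULL` where
#'   missing), `delta` (K per 1% NDVI), `class`, `coverage` (by precip),
#'   `reduction` (`vt_reduction`), `n_missing`.
#' @export
assess_tropics <- function(scene, cfg = analysis_config(),
                           mask_mode = "igbp_bare") {
  fields <- scene$fields
  pn <- scene$panel
  npix <- nrow(fields)
  veg <- vegetated_mask(fvc_mean = fields$fvc_mean,
                        landcover = fields$landcover, mode = mask_mode)
  delta <- rep(NA_real_, npix)
  cls <- factor(rep(NA_character_, npix),
                levels = c("cooling", "neutral", "warming"))
  fits <- vector("list", npix)
  for (px in which(veg)) {
    f <- fit_lst_drivers(pn$ndvi[px, ], pn$lst[px, ], pn$p[px, ], pn$rs[px, ],
                         alpha = cfg$alpha_level)
    if (is.null(f)) next
    fits[[px]] <- f
    mn <- mean(pn$ndvi[px, ], na.rm = TRUE)
    delta[px] <- delta_lst(f, mn)
    cls[px] <- if (f$p_ndvi < cfg$alpha_level) {
      if (f$beta_ndvi < 0) "cooling" else "warming"
    } else "neutral"
  }
  dry <- dryland_mask(fields$precip_annual, cfg$dryland_threshold) == "dryland"
  red <- dryland_cooling_reduction(delta[veg], dry[veg])
  structure(list(fits = fits, delta = delta, class = cls,
                 coverage = coverage_by_precip(cls[veg],
                                               fields$precip_annual[veg]),
                 reduction = red,
                 n_missing = sum(veg & is.na(delta))),
            class = "vt_assessment3")
}

#' @export
print.vt_assessment3 <- function(x, ...) {
  cat("<vt_assessment3> interannual NDVI effect on LST\n")
  cat(sprintf("  fitted pixels: %d (missing %d)\n",
              sum(!is.na(x$delta)), x$n_missing))
  print(x$reduction)
  invisible(x)
}
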