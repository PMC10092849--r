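# Synthetic satellite-scene generator. Produces a scene with the exact
# statistical structure the attribution pipeline assumes -- an aridity
# gradient, FVC-dependent morning warming rates, aridity-dependent albedo
# slopes, seasonal environmental cycles, 19-year annual panels -- together
# with the planted generative parameters (the truth bundle) so every stage
# can be checked by parameter recovery.

# Piecewise-linear planted FVC effect on the morning warming rate
# (K h-1 per unit FVC) along the precipitation gradient: warming (+1) at
# the arid end, an exactly-neutral band, then strengthening cooling to -5
# in humid terrain. The flat zero band gives the truth classification an
# honest neutral class.
.default_beta_fvc_profile <- function(precip) {
  b <- numeric(length(precip))
  b[precip <= 400] <- 1
  i <- precip > 400 & precip < 440
  b[i] <- 1 - (precip[i] - 400) / 40
  i <- precip > 560 & precip < 1160
  b[i] <- -5 * (precip[i] - 560) / 600
  b[precip >= 1160] <- -5
  b
}

# Dryland albedo declines twice as fast with FVC as humid albedo
# (-0.025 vs -0.0125 per 0.1 FVC).
.default_beta_albedo_profile <- function(precip) {
  ifelse(precip < 500, -0.25, -0.125)
}

#' Synthetic scene configuration
#'
#' Defaults describe a tropical dryland-to-humid transect: annual
#' precipitation spanning 100-1500 mm yr-1 (28.6% of pixels below the
#' 500 mm dryland line), soil moisture and FVC increasing and shortwave
#' radiation decreasing smoothly with rainfall, a planted FVC effect on
#' the morning warming rate running from +1 K h-1 per unit FVC (arid)
#' through an exact-zero neutral band to -5 K h-1 (humid), albedo-FVC
#' slopes of -0.25 (dryland) vs -0.125 (humid) per unit FVC, seasonal
#' cycles whose dryland low-vegetation season is 16% drier, 12% sunnier
#' and 6% higher-VPD than the annual mean, and 19-year annual panels with
#' planted NDVI/precipitation/radiation coefficients sized so a 1%
#' greening cools drylands by 0.05 K and humid pixels by 0.10 K.
#'
#' @param nx,ny pixel counts along the aridity gradient (x) and across it (y).
#' @param n_days days of 15-min LST sampling (one seasonal cycle).
#' @param time_step LST sampling interval in minutes; must divide 60.
#' @param aridity_gradient range of annual precipitation (mm yr-1) spanned
#'   smoothly along x.
#' @param beta_fvc_true planted FVC effect on the morning warming rate:
#'   a scalar (K h-1 per unit FVC) or a function of precipitation.
#' @param beta_albedo_true planted albedo-FVC slope: scalar or function of
#'   precipitation (albedo per unit FVC).
#' @param r0_coef baseline-rate coefficients `c(a, b_theta, b_rs)` so that
#'   the non-vegetation part of the morning slope is
#'   `a + b_theta * theta + b_rs * rs` (K h-1); shared by all pixels so
#'   conditioning bins share baselines.
#' @param k_relax relaxation rate (h-1) used by [relaxation_cube()].
#' @param noise_sd_lst LST noise scale (K): added per 15-min sample, and at
#'   `noise_sd_lst * 1 h^-1` as day-to-day jitter of the morning slope.
#' @param fvc_noise_sd pixel-level FVC noise (clipped to [0, 1]).
#' @param fvc_spread deterministic within-column FVC range (peak to peak),
#'   giving conditioning bins regressor variance even in noise-free mode.
#' @param noise_sd_albedo pixel-level albedo noise.
#' @param cloud_gap_prob independent probability a 15-min sample is QC-invalid.
#' @param seasonal_amp relative seasonal amplitudes of FVC, soil moisture,
#'   shortwave radiation and VPD (negative = out of phase with vegetation).
#' @param env_day_noise_sd day-level noise sds for FVC, theta, R_S, VPD.
#' @param n_years years in the annual panel.
#' @param beta_ndvi_true planted interannual NDVI effect on annual LST:
#'   scalar (K per NDVI unit) or function of (precip, ndvi_mean). The
#'   default plants -5 / ndvi_mean in drylands and -10 / ndvi_mean in humid
#'   pixels, i.e. Delta-LST of -0.05 and -0.10 K per 1% NDVI increase.
#' @param beta_p_true,beta_rs_true planted controls (K per mm yr-1, K per W m-2).
#' @param interannual_noise_sd annual LST noise (K).
#' @param ndvi_interannual_sd interannual NDVI variability.
#' @param trend_slope optional linear LST trend (K yr-1) added to the panel.
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return list of class `vt_scene_config`.
#' @export
scene_config <- function(nx = 20, ny = 20, n_days = 40, time_step = 15,
                         aridity_gradient = c(100, 1500),
                         beta_fvc_true = .default_beta_fvc_profile,
                         beta_albedo_true = .default_beta_albedo_profile,
                         r0_coef = c(0.5, 10, 0.008),
                         k_relax = 0.1,
                         noise_sd_lst = 0.3,
                         fvc_noise_sd = 0.08,
                         fvc_spread = 0.2,
                         noise_sd_albedo = 0.01,
                         cloud_gap_prob = 0.15,
                         seasonal_amp = c(fvc = 0.3, theta = 0.25,
                                          rs = -0.19, vpd = -0.094),
                         env_day_noise_sd = c(fvc = 0.008, theta = 0.002,
                                              rs = 3, vpd = 0.5),
                         n_years = 19,
                         beta_ndvi_true = function(precip, ndvi_mean)
                           ifelse(precip < 500, -5, -10) / pmax(ndvi_mean, 0.05),
                         beta_p_true = -0.003,
                         beta_rs_true = 0.02,
                         interannual_noise_sd = 0.3,
                         ndvi_interannual_sd = 0.03,
                         trend_slope = 0,
                         seed = 1L) {
  if (nx * ny <= 0 || n_days < 1) stop("degenerate scene: need nx*ny >= 1 and n_days >= 1")
  if (60 %% time_step != 0) stop("time_step must divide 60 minutes")
  if (cloud_gap_prob < 0 || cloud_gap_prob > 1) stop("cloud_gap_prob must lie in [0, 1]")
  if (n_years < 1) stop("n_years must be >= 1")
  cfg <- list(nx = as.integer(nx), ny = as.integer(ny),
              n_days = as.integer(n_days), time_step = time_step,
              aridity_gradient = aridity_gradient,
              beta_fvc_true = beta_fvc_true,
              beta_albedo_true = beta_albedo_true,
              r0_coef = r0_coef, k_relax = k_relax,
              noise_sd_lst = noise_sd_lst, fvc_noise_sd = fvc_noise_sd,
              fvc_spread = fvc_spread, noise_sd_albedo = noise_sd_albedo,
              cloud_gap_prob = cloud_gap_prob, seasonal_amp = seasonal_amp,
              env_day_noise_sd = env_day_noise_sd, n_years = as.integer(n_years),
              beta_ndvi_true = beta_ndvi_true, beta_p_true = beta_p_true,
              beta_rs_true = beta_rs_true,
              interannual_noise_sd = interannual_noise_sd,
              ndvi_interannual_sd = ndvi_interannual_sd,
              trend_slope = trend_slope, seed = as.integer(seed))
  class(cfg) <- "vt_scene_config"
  cfg
}

#' Zero every stochastic term of a scene configuration
#'
#' Returns the same configuration with all noise standard deviations and
#' the cloud-gap probability set to zero, so the generated scene is an
#' exact realisation of the planted model (regressor spread from the
#' deterministic within-column FVC gradient is retained).
#'
#' @param cfg a `vt_scene_config`.
#' @return modified `vt_scene_config`.
#' @export
noise_free <- function(cfg) {
  cfg$noise_sd_lst <- 0
  cfg$fvc_noise_sd <- 0
  cfg$noise_sd_albedo <- 0
  cfg$cloud_gap_prob <- 0
  cfg$env_day_noise_sd[] <- 0
  cfg$interannual_noise_sd <- 0
  cfg$ndvi_interannual_sd <- 0
  cfg
}

.as_profile <- function(x) if (is.function(x)) x else function(p, ...) rep_len(x, length(p))

# Seasonal carrier: one full sine cycle over the sampled days, centred so
# its mean is exactly zero (annual means of seasonal fields equal the
# long-term means to machine precision).
.seasonal_carrier <- function(n_days) {
  s <- sin(2 * pi * (seq_len(n_days) - 0.5) / n_days)
  s - mean(s)
}

# Piecewise-linear diurnal LST template: flat pre-dawn, linear morning ramp
# 06:00-12:00 with slope r, plateau to 14:30, linear decay to the base by
# 24:00. Gives the morning-rate statistic an exact analytic truth and makes
# DTR = 6 h * slope.
.diurnal_template <- function(times, r, lst0 = 290) {
  shape <- numeric(length(times))
  i <- times >= 6 & times < 12
  shape[i] <- times[i] - 6
  i <- times >= 12 & times <= 14.5
  shape[i] <- 6
  i <- times > 14.5
  shape[i] <- 6 * (1 - (times[i] - 14.5) / 9.5)
  outer(r, shape) + lst0
}

#' Generate a synthetic scene with planted parameters
#'
#' Builds the full input bundle of the attribution pipeline on an
#' `nx * ny` lattice: static fields varying smoothly along the aridity
#' gradient, a 15-min diurnal LST cube whose morning slope is
#' `r0(theta, rs) + beta_fvc_true * FVC` plus noise, day-level seasonal
#' series of FVC/theta/R_S/VPD, an annual NDVI/LST/P/R_S panel with
#' planted coefficients, independent QC cloud gaps, and the truth bundle
#' of all planted parameters.
#'
#' @param cfg a [scene_config()].
#' @return list of class `vt_scene` with elements `domain`, `fields`,
#'   `cube` (`vt_cube`), `daily` (pixel-by-day matrices `fvc`, `theta`,
#'   `rs`, `vpd`), `panel` (pixel-by-year matrices `ndvi`, `lst`, `p`,
#'   `rs`), `truth` (`vt_truth`) and `config`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "vt_scene_config"))
  set.seed(cfg$seed)
  nx <- cfg$nx; ny <- cfg$ny; npix <- nx * ny; nd <- cfg$n_days

  # lattice: x = aridity gradient, y = within-climate spread
  ix <- rep(seq_len(nx), each = ny)
  iy <- rep(seq_len(ny), times = nx)
  lat <- -10 + 20 * (iy - 1) / max(ny - 1, 1)
  lon <- 10 + 30 * (ix - 1) / max(nx - 1, 1)
  domain <- grid_domain(lat, lon, cell_size = 9)

  # static fields along the gradient
  g <- if (nx > 1) (ix - 1) / (nx - 1) else rep(0.5, npix)
  precip <- cfg$aridity_gradient[1] + diff(cfg$aridity_gradient) * g
  theta <- 0.04 + 2e-4 * precip
  rs <- 300 - 0.06 * precip
  fvc_base <- 0.08 + 0.9 * (precip - 100) / 1400
  yspread <- if (ny > 1) cfg$fvc_spread * ((iy - 1) / (ny - 1) - 0.5) else 0
  fvc <- pmin(pmax(fvc_base + yspread + rnorm(npix, 0, cfg$fvc_noise_sd), 0), 1)
  beta_fvc <- .as_profile(cfg$beta_fvc_true)(precip)
  beta_alb <- .as_profile(cfg$beta_albedo_true)(precip)
  a0 <- 0.38 - 1e-4 * precip
  albedo <- pmin(pmax(a0 + beta_alb * fvc + rnorm(npix, 0, cfg$noise_sd_albedo), 0), 1)
  vpd <- 30 - 0.015 * precip
  landcover <- ifelse(precip < 150, 16L, ifelse(precip < 450, 7L,
                 ifelse(precip < 700, 10L, ifelse(precip < 1000, 9L, 2L))))
  fields <- field_stack(fvc, theta, rs, albedo, vpd, precip, landcover, domain)

  # day-level seasonal environment (pixel x day)
  s <- .seasonal_carrier(nd)
  amp <- cfg$seasonal_amp
  amp_theta_px <- 1 + rnorm(npix, 0, 0.2)
  amp_rs_px <- 1 + rnorm(npix, 0, 0.2)
  en <- cfg$env_day_noise_sd
  fvc_day <- pmin(pmax(outer(fvc, 1 + amp[["fvc"]] * s) +
                         rnorm(npix * nd, 0, en[["fvc"]]), 0), 1)
  dim(fvc_day) <- c(npix, nd)
  theta_day <- theta * (1 + outer(amp_theta_px * amp[["theta"]], s)) +
    rnorm(npix * nd, 0, en[["theta"]])
  dim(theta_day) <- c(npix, nd)
  rs_day <- rs * (1 + outer(amp_rs_px * amp[["rs"]], s)) +
    rnorm(npix * nd, 0, en[["rs"]])
  dim(rs_day) <- c(npix, nd)
  vpd_day <- vpd * (1 + outer(rep(1, npix) * amp[["vpd"]], s)) +
    rnorm(npix * nd, 0, en[["vpd"]])
  dim(vpd_day) <- c(npix, nd)

  # daily morning slope (K/h) and the diurnal cube
  r0 <- cfg$r0_coef[1] + cfg$r0_coef[2] * theta_day + cfg$r0_coef[3] * rs_day
  r_day <- r0 + beta_fvc * fvc_day + rnorm(npix * nd, 0, cfg$noise_sd_lst)
  times <- seq(0, 24 - cfg$time_step / 60, by = cfg$time_step / 60)
  nt <- length(times)
  lst <- array(NA_real_, c(npix, nd, nt))
  for (d in seq_len(nd)) lst[, d, ] <- .diurnal_template(times, r_day[, d])
  if (cfg$noise_sd_lst > 0)
    lst <- lst + array(rnorm(npix * nd * nt, 0, cfg$noise_sd_lst), dim(lst))
  qc <- array(runif(npix * nd * nt) >= cfg$cloud_gap_prob, c(npix, nd, nt))
  cube <- structure(list(lst = lst, qc = qc, times = times, lon = lon),
                    class = "vt_cube")

  # annual panel (pixel x year)
  nyrs <- cfg$n_years
  ndvi_mean <- 0.1 + 4e-4 * precip
  bn <- if (is.function(cfg$beta_ndvi_true))
    cfg$beta_ndvi_true(precip, ndvi_mean) else rep_len(cfg$beta_ndvi_true, npix)
  ndvi_y <- ndvi_mean + matrix(rnorm(npix * nyrs, 0, cfg$ndvi_interannual_sd), npix)
  p_y <- precip * (1 + matrix(rnorm(npix * nyrs, 0, 0.1), npix))
  rs_y <- rs + matrix(rnorm(npix * nyrs, 0, 5), npix)
  yr_c <- seq_len(nyrs) - (nyrs + 1) / 2
  lst_y <- 300 + bn * ndvi_y + cfg$beta_p_true * p_y + cfg$beta_rs_true * rs_y +
    matrix(rnorm(npix * nyrs, 0, cfg$interannual_noise_sd), npix) +
    outer(rep(cfg$trend_slope, npix), yr_c)
  panel <- list(ndvi = ndvi_y, lst = lst_y, p = p_y, rs = rs_y,
                years = seq_len(nyrs))

  truth <- structure(list(
    beta_fvc_true = beta_fvc,
    beta_albedo_true = beta_alb,
    beta_eff_true = rep(NA_real_, npix),
    beta_ndvi_true = bn,
    ndvi_mean_true = ndvi_mean,
    delta_lst_true = bn * 0.01 * ndvi_mean,
    effect_class_true = factor(ifelse(beta_fvc < 0, "cooling",
                                      ifelse(beta_fvc > 0, "warming", "neutral")),
                               levels = c("cooling", "neutral", "warming")),
    r0_coef = cfg$r0_coef), class = "vt_truth")

  structure(list(domain = domain, fields = fields, cube = cube,
                 daily = list(fvc = fvc_day, theta = theta_day,
                              rs = rs_day, vpd = vpd_day),
                 panel = panel, truth = truth, config = cfg),
            class = "vt_scene")
}

#' @export
print.vt_scene <- function(x, ...) {
  cat(sprintf("<vt_scene> %d x %d pixels, %d days at %g-min LST sampling, %d-year panel\n",
              x$config$nx, x$config$ny, x$config$n_days, x$config$time_step,
              x$config$n_years))
  cat(sprintf("  precip %g-%g mm/yr; dryland fraction %.1f%%\n",
              min(x$fields$precip_annual), max(x$fields$precip_annual),
              100 * mean(x$fields$precip_annual < 500)))
  invisible(x)
}

#' Exponential-relaxation LST cube
#'
#' Single-pixel diurnal cube following
#' `LST(t) = lst_eq - (lst_eq - lst0) * exp(-k_relax * t)`, the
#' force-restore form in which the warming rate is proportional to the
#' departure from equilibrium. Sampled finite-difference rates regressed on
#' midpoint LST then have the exact slope `-(2/dt) * tanh(k_relax * dt / 2)`,
#' the oracle for the energy-dissipation-efficiency fit.
#'
#' @param k_relax relaxation rate (h-1), > 0.
#' @param lst_eq equilibrium LST (K), must exceed `lst0`.
#' @param lst0 initial LST (K) at t = 0.
#' @param time_step sampling interval (minutes).
#' @param hours record length (h).
#' @param noise_sd optional Gaussian sample noise (K).
#' @return a `vt_cube` with one pixel and one day.
#' @export
relaxation_cube <- function(k_relax, lst_eq = 320, lst0 = 290,
                            time_step = 15, hours = 24, noise_sd = 0) {
  if (k_relax <= 0) stop("k_relax must be > 0")
  if (lst_eq <= lst0) stop("lst_eq must exceed lst0")
  times <- seq(0, hours - time_step / 60, by = time_step / 60)
  y <- lst_eq - (lst_eq - lst0) * exp(-k_relax * times)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  lst <- array(y, c(1, 1, length(times)))
  structure(list(lst = lst,
                 qc = array(TRUE, dim(lst)),
                 times = times, lon = 0),
            class = "vt_cube")
}
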