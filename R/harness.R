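# Domain model shared by all stages: pixel lattice, static field stack,
# masks and the analysis configuration.

#' Pixel lattice for a co-gridded scene
#'
#' All inputs to the attribution pipeline are assumed co-registered on one
#' equal-area pixel lattice (regridding is a precondition, not a feature).
#' Pixel ids are contiguous integers starting at 0.
#'
#' @param lat,lon numeric vectors of pixel centre coordinates (degrees).
#' @param cell_size grid cell size (km for an equal-area grid).
#' @return An object of class `vt_grid` with fields `pixel_id`, `lat`,
#'   `lon`, `cell_size`, `n_pixels`.
#' @export
grid_domain <- function(lat, lon, cell_size = 9) {
  if (length(lat) != length(lon)) stop("lat and lon must have equal length")
  if (length(lat) == 0L) stop("empty domain")
  if (any(!is.finite(lat)) || any(abs(lat) > 90)) stop("lat must be finite in [-90, 90]")
  if (any(!is.finite(lon)) || any(abs(lon) > 180)) stop("lon must be finite in [-180, 180]")
  structure(list(pixel_id = seq_along(lat) - 1L, lat = as.numeric(lat),
                 lon = as.numeric(lon), cell_size = cell_size,
                 n_pixels = length(lat)),
            class = "vt_grid")
}

#' @export
print.vt_grid <- function(x, ...) {
  cat(sprintf("<vt_grid> %d pixels, cell size %s km\n", x$n_pixels,
              format(x$cell_size)))
  invisible(x)
}

# Canonical units carried by the static field stack.
.vt_field_units <- c(fvc_mean = "1", theta_mean = "m3 m-3", rs_mean = "W m-2",
                     albedo_mean = "1", vpd_mean = "hPa",
                     precip_annual = "mm yr-1", landcover = "IGBP code")

#' Static per-pixel field stack
#'
#' Long-term mean fields aligned to one [grid_domain()]: fraction of
#' vegetation cover (FVC), soil moisture, downwelling shortwave radiation,
#' surface albedo, vapour pressure deficit, total annual precipitation and
#' an IGBP-style land-cover code. Unit metadata is attached and checked on
#' I/O; operations reject mismatched units rather than converting silently.
#'
#' @param fvc_mean,albedo_mean fractions in [0, 1].
#' @param theta_mean volumetric soil moisture (m3 m-3).
#' @param rs_mean downwelling shortwave radiation (W m-2).
#' @param vpd_mean vapour pressure deficit (hPa).
#' @param precip_annual total annual precipitation (mm yr-1), non-negative.
#' @param landcover integer IGBP class codes (1-17; 16 = barren).
#' @param domain a `vt_grid`; lengths must match its pixel count.
#' @return A `data.frame` of class `vt_fields` with a `units` attribute.
#' @export
field_stack <- function(fvc_mean, theta_mean, rs_mean, albedo_mean,
                        vpd_mean, precip_annual, landcover, domain) {
  n <- domain$n_pixels
  f <- data.frame(fvc_mean = as.numeric(fvc_mean),
                  theta_mean = as.numeric(theta_mean),
                  rs_mean = as.numeric(rs_mean),
                  albedo_mean = as.numeric(albedo_mean),
                  vpd_mean = as.numeric(vpd_mean),
                  precip_annual = as.numeric(precip_annual),
                  landcover = as.integer(landcover))
  if (nrow(f) != n) stop("fields are not aligned to the grid domain")
  for (nm in c("fvc_mean", "albedo_mean")) {
    v <- f[[nm]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) stop(nm, " must lie in [0, 1]")
  }
  if (any(f$precip_annual < 0, na.rm = TRUE)) stop("precip_annual must be >= 0")
  if (any(!f$landcover %in% 1:17)) stop("unknown IGBP landcover code")
  attr(f, "units") <- .vt_field_units
  class(f) <- c("vt_fields", "data.frame")
  f
}

# IGBP barren-land code used by the bare-soil removal mask.
IGBP_BARREN <- 16L

#' Dryland / humid classification by annual precipitation
#'
#' Drylands are vegetated surfaces receiving less than `threshold` mm of
#' rainfall per year; the comparison is strict, so a pixel exactly at the
#' threshold is humid. Used both at the default 500 mm split and at the
#' +/-200 mm sensitivity thresholds.
#'
#' @param precip_annual numeric vector, mm yr-1, finite and non-negative.
#' @param threshold dryland threshold (mm yr-1), default 500.
#' @return factor with levels `dryland`, `humid`.
#' @export
dryland_mask <- function(precip_annual, threshold = 500) {
  if (any(!is.finite(precip_annual)) || any(precip_annual < 0))
    stop("precip_annual must be finite and >= 0")
  factor(ifelse(precip_annual < threshold, "dryland", "humid"),
         levels = c("dryland", "humid"))
}

#' Vegetated-pixel mask
#'
#' Two removal rules for non-vegetated surfaces: `fvc_zero` drops pixels
#' whose long-term mean FVC is exactly zero; `igbp_bare` drops pixels whose
#' IGBP land-cover class is barren.
#'
#' @param fvc_mean mean FVC per pixel (mode `fvc_zero`).
#' @param landcover IGBP codes per pixel (mode `igbp_bare`).
#' @param mode which rule to apply.
#' @return logical vector, `TRUE` for retained (vegetated) pixels.
#' @export
vegetated_mask <- function(fvc_mean = NULL, landcover = NULL,
                           mode = c("fvc_zero", "igbp_bare")) {
  mode <- match.arg(mode)
  if (mode == "fvc_zero") {
    if (is.null(fvc_mean)) stop("fvc_mean required for mode 'fvc_zero'")
    if (any(fvc_mean < 0 | fvc_mean > 1, na.rm = TRUE)) stop("fvc_mean must lie in [0, 1]")
    fvc_mean > 0
  } else {
    if (is.null(landcover)) stop("landcover required for mode 'igbp_bare'")
    if (any(!landcover %in% 1:17)) stop("unknown IGBP landcover code")
    landcover != IGBP_BARREN
  }
}

#' Analysis configuration
#'
#' Tunable parameters of the attribution pipeline with their field-standard
#' defaults: conditioning-bin half-widths of 0.0025 m3 m-3 (soil moisture)
#' and 1.25 W m-2 (shortwave radiation), the 500 mm yr-1 dryland threshold
#' with a +/-200 mm sensitivity band, the 07:00-11:00 local-solar morning
#' window, the 13:30/06:00 diurnal-range sample times and the 12:30-14:30
#' afternoon window.
#'
#' @param theta_half_width soil-moisture bin half-width (m3 m-3).
#' @param rs_half_width shortwave-radiation bin half-width (W m-2).
#' @param dryland_threshold dryland precipitation threshold (mm yr-1).
#' @param dryland_sensitivity sensitivity band around the threshold (mm yr-1).
#' @param alpha_level two-sided significance level for effect classification.
#' @param fvc_report_step FVC step used for reported effect sizes (0.1).
#' @param morning_window half-open local-solar window (h) for d(LST)/dt.
#' @param afternoon_window closed local-solar window (h) for afternoon mean LST.
#' @param dtr_times local-solar hours taken as daily max and min LST.
#' @param min_pixels_per_regressor minimum bin pixels per fitted coefficient.
#' @param min_valid_days minimum valid days for an annual-mean rate.
#' @param max_gap_hours longest QC gap a rate increment may span (h).
#' @param bootstrap_reps bootstrap resamples for group contrasts.
#' @param seed optional integer seed recorded with results.
#' @return list of class `vt_config`.
#' @export
analysis_config <- function(theta_half_width = 0.0025, rs_half_width = 1.25,
                            dryland_threshold = 500, dryland_sensitivity = 200,
                            alpha_level = 0.05, fvc_report_step = 0.1,
                            morning_window = c(7, 11),
                            afternoon_window = c(12.5, 14.5),
                            dtr_times = c(13.5, 6),
                            min_pixels_per_regressor = 10,
                            min_valid_days = 30,
                            max_gap_hours = 2,
                            bootstrap_reps = 1000,
                            seed = NULL) {
  stopifnot(theta_half_width > 0, rs_half_width > 0,
            alpha_level > 0, alpha_level < 1,
            min_pixels_per_regressor >= 1, max_gap_hours > 0)
  chk_win <- function(w) all(is.finite(w)) && length(w) == 2 &&
    w[1] >= 0 && w[2] <= 24 && w[1] < w[2]
  if (!chk_win(morning_window) || !chk_win(afternoon_window))
    stop("time windows must lie within [0, 24) hours")
  structure(list(theta_half_width = theta_half_width,
                 rs_half_width = rs_half_width,
                 dryland_threshold = dryland_threshold,
                 dryland_sensitivity = dryland_sensitivity,
                 alpha_level = alpha_level,
                 fvc_report_step = fvc_report_step,
                 morning_window = morning_window,
                 afternoon_window = afternoon_window,
                 dtr_times = dtr_times,
                 min_pixels_per_regressor = min_pixels_per_regressor,
                 min_valid_days = min_valid_days,
                 max_gap_hours = max_gap_hours,
                 bootstrap_reps = bootstrap_reps,
                 seed = seed),
            class = "vt_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take [analysis_config()] defaults.
#'
#' @param path path to a YAML file.
#' @return list of class `vt_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}
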