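# Diurnal LST statistics: 15-min finite-difference warming rates over the
# morning window, daily medians, diurnal temperature range and window-mean
# temperatures. Missingness (cloud-gapped QC) is a first-class value that
# propagates from samples to daily and annual statistics.

#' Convert UTC hours to local solar time
#'
#' @param utc decimal hours UTC.
#' @param lon longitude in degrees, East positive.
#' @return decimal hours in [0, 24).
#' @export
local_solar_time <- function(utc, lon) {
  if (any(abs(lon) > 180, na.rm = TRUE)) stop("lon must lie in [-180, 180]")
  (utc + lon / 15) %% 24
}

#' Sub-daily finite-difference warming rates for one pixel-day
#'
#' Differences each pair of time-adjacent *valid* LST samples inside the
#' window and divides by the elapsed time; QC-flagged samples are skipped,
#' so an increment may span more than one sampling interval, up to
#' `max_gap` hours (longer gaps yield no increment). The midpoint LST of
#' each increment is retained for the dissipation-efficiency regression.
#'
#' @param lst numeric LST samples (K).
#' @param qc logical validity flags (TRUE = valid).
#' @param times sample times in decimal hours, strictly increasing.
#' @param window half-open `[start, end)` window in hours, or `NULL` for all.
#' @param max_gap maximum hours an increment may span.
#' @return data.frame with columns `rate` (K h-1) and `mid_lst` (K); zero
#'   rows when fewer than two valid samples fall in the window.
#' @export
subdaily_rates <- function(lst, qc = NULL, times, window = c(7, 11),
                           max_gap = 2) {
  if (is.null(qc)) qc <- rep(TRUE, length(lst))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  keep <- qc & is.finite(lst)
  if (!is.null(window)) keep <- keep & times >= window[1] & times < window[2]
  x <- lst[keep]; tt <- times[keep]
  if (length(x) < 2)
    return(data.frame(rate = numeric(0), mid_lst = numeric(0)))
  dt <- diff(tt)
  ok <- dt <= max_gap + 1e-9
  data.frame(rate = (diff(x) / dt)[ok],
             mid_lst = ((x[-1] + x[-length(x)]) / 2)[ok])
}

#' Daily median warming rate
#'
#' Median of all available sub-daily rate increments for one day; an empty
#' increment list yields a missing value, not an error.
#'
#' @param rates numeric vector of sub-daily rates (K h-1), possibly empty.
#' @return median rate (K h-1) or `NA_real_`.
#' @export
daily_median_rate <- function(rates) {
  if (length(rates) == 0) return(NA_real_)
  stats::median(rates)
}

# All rate increments of a cube at once: collapse (pixel, day) into rows,
# walk valid samples in time order, difference adjacent ones. Returns a
# data.table with pixel, day, rate (K/h) and midpoint LST.
cube_rates <- function(cube, window = c(7, 11), max_gap = 2) {
  times <- cube$times
  sel <- if (is.null(window)) rep(TRUE, length(times)) else
    times >= window[1] & times < window[2]
  tw <- times[sel]
  dm <- dim(cube$lst)
  npix <- dm[1]; nday <- dm[2]
  m <- cube$lst[, , sel, drop = FALSE]
  dim(m) <- c(npix * nday, length(tw))
  v <- cube$qc[, , sel, drop = FALSE]
  dim(v) <- dim(m)
  v <- v & is.finite(m)
  iv <- which(v)
  nr <- nrow(m)
  row <- (iv - 1L) %% nr + 1L
  col <- (iv - 1L) %/% nr + 1L
  o <- order(row, col)
  row <- row[o]; col <- col[o]
  x <- m[iv][o]
  n <- length(x)
  if (n < 2)
    return(data.table::data.table(pixel = integer(0), day = integer(0),
                                  rate = numeric(0), mid_lst = numeric(0)))
  same <- row[-1] == row[-n]
  dt <- tw[col[-1]] - tw[col[-n]]
  keep <- same & dt <= max_gap + 1e-9
  data.table::data.table(
    pixel = (row[-n][keep] - 1L) %% npix + 1L,
    day = (row[-n][keep] - 1L) %/% npix + 1L,
    rate = ((x[-1] - x[-n]) / dt)[keep],
    mid_lst = ((x[-1] + x[-n]) / 2)[keep])
}

#' Diurnal temperature range per pixel-day
#'
#' DTR = LST(13:30) - LST(06:00), the assumed daily maximum minus minimum;
#' missing wherever either sample is QC-invalid.
#'
#' @param cube a `vt_cube`.
#' @param times the two local-solar hours (max, min).
#' @return pixel-by-day matrix of DTR (K).
#' @export
diurnal_range <- function(cube, times = c(13.5, 6)) {
  i_hi <- which(abs(cube$times - times[1]) < 1e-9)
  i_lo <- which(abs(cube$times - times[2]) < 1e-9)
  if (length(i_hi) != 1 || length(i_lo) != 1)
    stop("cube does not sample the requested DTR times")
  hi <- cube$lst[, , i_hi, drop = TRUE]
  lo <- cube$lst[, , i_lo, drop = TRUE]
  ok <- cube$qc[, , i_hi, drop = TRUE] & cube$qc[, , i_lo, drop = TRUE]
  out <- hi - lo
  out[!ok] <- NA_real_
  if (is.null(dim(out))) out <- matrix(out, nrow = dim(cube$lst)[1])
  out
}

#' Window-mean LST per pixel
#'
#' Mean over valid samples inside a closed time window for each pixel-day,
#' then over days; missing when no valid sample exists.
#'
#' @param cube a `vt_cube`.
#' @param window closed `[start, end]` window in hours.
#' @param by `"pixel"` for the annual mean, `"pixel_day"` for the daily matrix.
#' @return numeric vector (per pixel) or pixel-by-day matrix (K).
#' @export
window_mean_lst <- function(cube, window, by = c("pixel", "pixel_day")) {
  by <- match.arg(by)
  sel <- cube$times >= window[1] - 1e-9 & cube$times <= window[2] + 1e-9
  if (!any(sel)) stop("window contains no samples")
  x <- cube$lst[, , sel, drop = FALSE]
  q <- cube$qc[, , sel, drop = FALSE]
  x[!q] <- NA_real_
  daily <- apply(x, c(1, 2), function(z) mean(z, na.rm = TRUE))
  daily[is.nan(daily)] <- NA_real_
  if (by == "pixel_day") return(daily)
  out <- rowMeans(daily, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Rate statistics for a diurnal cube
#'
#' The full per-pixel statistic set: daily median morning d(LST)/dt, its
#' annual mean (missing unless at least `min_valid_days` days have a
#' rate), daily and annual-mean DTR, and afternoon/morning mean LST.
#'
#' @param cube a `vt_cube`.
#' @param cfg an [analysis_config()].
#' @return list of class `vt_rate_map` with `rate_daily` (pixel x day),
#'   `rate_annual`, `dtr_daily`, `dtr_annual`, `afternoon_mean`,
#'   `morning_mean` and `n_valid_days`.
#' @export
rate_map <- function(cube, cfg = analysis_config()) {
  dm <- dim(cube$lst)
  npix <- dm[1]; nday <- dm[2]
  inc <- cube_rates(cube, window = cfg$morning_window,
                    max_gap = cfg$max_gap_hours)
  rate_daily <- matrix(NA_real_, npix, nday)
  if (nrow(inc)) {
    med <- inc[, list(rate = stats::median(rate)), by = c("pixel", "day")]
    rate_daily[cbind(med$pixel, med$day)] <- med$rate
  }
  nvd <- rowSums(!is.na(rate_daily))
  rate_annual <- rowMeans(rate_daily, na.rm = TRUE)
  rate_annual[is.nan(rate_annual) | nvd < min(cfg$min_valid_days, nday)] <- NA_real_
  dtr_daily <- diurnal_range(cube, cfg$dtr_times)
  dtr_annual <- rowMeans(dtr_daily, na.rm = TRUE)
  dtr_annual[is.nan(dtr_annual)] <- NA_real_
  structure(list(rate_daily = rate_daily, rate_annual = rate_annual,
                 dtr_daily = dtr_daily, dtr_annual = dtr_annual,
                 afternoon_mean = window_mean_lst(cube, cfg$afternoon_window),
                 morning_mean = window_mean_lst(cube, c(6, 6)),
                 n_valid_days = nvd),
            class = "vt_rate_map")
}

#' @export
print.vt_rate_map <- function(x, ...) {
  cat(sprintf("<vt_rate_map> %d pixels x %d days; annual rate available for %d pixels\n",
              nrow(x$rate_daily), ncol(x$rate_daily), sum(!is.na(x$rate_annual))))
  invisible(x)
}

#' Spatial correlation between the morning rate and DTR
#'
#' Pearson correlation across pixels, per day, between the daily median
#' morning d(LST)/dt and the 13:30 - 06:00 diurnal temperature range.
#'
#' @param rate_daily pixel-by-day matrix of daily median rates (K h-1).
#' @param dtr_daily pixel-by-day matrix of DTR (K).
#' @return numeric vector, one correlation per day; `NA` with a
#'   `"degenerate"` attribute entry when either field has zero spatial
#'   variance or fewer than 3 pixels carry both statistics.
#' @export
rate_dtr_correlation <- function(rate_daily, dtr_daily) {
  stopifnot(all(dim(rate_daily) == dim(dtr_daily)))
  nday <- ncol(rate_daily)
  out <- rep(NA_real_, nday)
  degen <- logical(nday)
  for (d in seq_len(nday)) {
    ok <- !is.na(rate_daily[, d]) & !is.na(dtr_daily[, d])
    if (sum(ok) < 3) { degen[d] <- TRUE; next }
    if (stats::sd(rate_daily[ok, d]) == 0 || stats::sd(dtr_daily[ok, d]) == 0) {
      degen[d] <- TRUE; next
    }
    out[d] <- stats::cor(rate_daily[ok, d], dtr_daily[ok, d])
  }
  attr(out, "degenerate") <- degen
  out
}
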