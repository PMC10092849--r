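# Shared fixtures, built in code. Scenes are memoised per test session.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, cfg) {
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- generate_scene(cfg)
  .scene_cache[[key]]
}

# Mid-sized default-noise scene reused by several recovery tests.
default_scene <- function(seed = 42) {
  cached_scene(paste0("default", seed),
               scene_config(nx = 30, ny = 30, n_days = 40, seed = seed))
}

# Noise-free scene: every planted relation holds exactly.
exact_scene <- function(seed = 3) {
  cached_scene(paste0("exact", seed),
               noise_free(scene_config(nx = 15, ny = 25, n_days = 12,
                                       seed = seed)))
}

# Config matching the small scenes (short records).
small_cfg <- function(...) analysis_config(min_valid_days = 10, ...)

# Exact piecewise-ramp cube for one pixel: slope r (K/h) from 06:00 to
# 12:00, plateau to 14:30, linear decay after; optional QC gaps.
ramp_cube <- function(r, n_days = 5, lst0 = 290, gap_prob = 0,
                      time_step = 15) {
  times <- seq(0, 24 - time_step / 60, by = time_step / 60)
  shape <- numeric(length(times))
  shape[times >= 6 & times < 12] <- times[times >= 6 & times < 12] - 6
  shape[times >= 12 & times <= 14.5] <- 6
  dec <- times > 14.5
  shape[dec] <- 6 * (1 - (times[dec] - 14.5) / 9.5)
  lst <- array(rep(lst0 + r * shape, each = n_days), c(1, n_days, length(times)))
  qc <- array(stats::runif(length(lst)) >= gap_prob, dim(lst))
  structure(list(lst = lst, qc = qc, times = times, lon = 0),
            class = "vt_cube")
}
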