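# Scene and result I/O. A scene is stored as a plain-text bundle: CSV
# tables for the gridded arrays plus JSON metadata carrying dimensions,
# unit attributes and the truth bundle. read_scene(write_scene(x))
# reproduces every field within floating-point text representation.

.scene_files <- c(meta = "meta.json", domain = "domain.csv",
                  fields = "fields.csv", cube = "cube_lst.csv",
                  daily = "daily_env.csv", panel = "annual_panel.csv",
                  truth = "truth.json")

#' Write a scene bundle
#'
#' @param scene a `vt_scene`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "vt_scene"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fp <- function(nm) file.path(path, .scene_files[[nm]])
  dm <- dim(scene$cube$lst)
  meta <- list(n_pixels = dm[1], n_days = dm[2], times = scene$cube$times,
               n_years = length(scene$panel$years),
               cell_size = scene$domain$cell_size,
               units = as.list(attr(scene$fields, "units")),
               lst_units = "K",
               seed = scene$config$seed)
  jsonlite::write_json(meta, fp("meta"), auto_unbox = TRUE, digits = NA)
  data.table::fwrite(data.frame(pixel_id = scene$domain$pixel_id,
                                lat = scene$domain$lat,
                                lon = scene$domain$lon), fp("domain"))
  data.table::fwrite(as.data.frame(scene$fields), fp("fields"))
  cube_long <- data.frame(
    pixel = rep(seq_len(dm[1]), times = dm[2] * dm[3]),
    day = rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
    time = rep(scene$cube$times, each = dm[1] * dm[2]),
    lst = as.vector(scene$cube$lst),
    qc = as.integer(as.vector(scene$cube$qc)))
  data.table::fwrite(cube_long, fp("cube"))
  nd <- ncol(scene$daily$fvc)
  daily_long <- data.frame(
    pixel = rep(seq_len(dm[1]), times = nd),
    day = rep(seq_len(nd), each = dm[1]),
    fvc = as.vector(scene$daily$fvc),
    theta = as.vector(scene$daily$theta),
    rs = as.vector(scene$daily$rs),
    vpd = as.vector(scene$daily$vpd))
  data.table::fwrite(daily_long, fp("daily"))
  ny <- length(scene$panel$years)
  panel_long <- data.frame(
    pixel = rep(seq_len(dm[1]), times = ny),
    year = rep(scene$panel$years, each = dm[1]),
    ndvi = as.vector(scene$panel$ndvi),
    lst = as.vector(scene$panel$lst),
    p = as.vector(scene$panel$p),
    rs = as.vector(scene$panel$rs))
  data.table::fwrite(panel_long, fp("panel"))
  tr <- scene$truth
  jsonlite::write_json(list(beta_fvc_true = tr$beta_fvc_true,
                            beta_albedo_true = tr$beta_albedo_true,
                            beta_eff_true = tr$beta_eff_true,
                            beta_ndvi_true = tr$beta_ndvi_true,
                            ndvi_mean_true = tr$ndvi_mean_true,
                            delta_lst_true = tr$delta_lst_true,
                            effect_class_true = as.character(tr$effect_class_true),
                            r0_coef = tr$r0_coef),
                       fp("truth"), digits = NA, na = "null")
  invisible(path)
}

#' Read a scene bundle
#'
#' Validates the bundle (every file and variable present, grid-aligned
#' lengths, unit metadata) and reconstructs the `vt_scene`; failures name
#' the missing piece.
#'
#' @param path directory written by [write_scene()].
#' @return a `vt_scene` (without the generating configuration functions).
#' @export
read_scene <- function(path) {
  fp <- function(nm) file.path(path, .scene_files[[nm]])
  for (nm in names(.scene_files))
    if (!file.exists(fp(nm)))
      stop("scene bundle is missing ", .scene_files[[nm]])
  meta <- jsonlite::read_json(fp("meta"), simplifyVector = TRUE)
  for (k in c("n_pixels", "n_days", "times", "units", "lst_units"))
    if (is.null(meta[[k]])) stop("meta.json is missing variable '", k, "'")
  if (!identical(meta$lst_units, "K")) stop("LST unit attribute must be 'K'")
  npix <- meta$n_pixels; nd <- meta$n_days; times <- meta$times
  if (npix < 1) stop("empty domain")
  need <- function(df, cols, file)
    for (cc in cols) if (is.null(df[[cc]]))
      stop(file, " is missing variable '", cc, "'")
  dom <- data.table::fread(fp("domain"), data.table = FALSE)
  need(dom, c("pixel_id", "lat", "lon"), "domain.csv")
  if (nrow(dom) != npix) stop("domain is misaligned with meta n_pixels")
  domain <- grid_domain(dom$lat, dom$lon, cell_size = meta$cell_size)
  fl <- data.table::fread(fp("fields"), data.table = FALSE)
  need(fl, names(.vt_field_units), "fields.csv")
  if (nrow(fl) != npix) stop("fields.csv is misaligned with the grid")
  fields <- field_stack(fl$fvc_mean, fl$theta_mean, fl$rs_mean,
                        fl$albedo_mean, fl$vpd_mean, fl$precip_annual,
                        fl$landcover, domain)
  cu <- data.table::fread(fp("cube"), data.table = FALSE)
  need(cu, c("pixel", "day", "time", "lst", "qc"), "cube_lst.csv")
  nt <- length(times)
  if (nrow(cu) != npix * nd * nt) stop("cube_lst.csv is misaligned with the grid")
  o <- order(cu$time, cu$day, cu$pixel)
  lst <- array(cu$lst[o], c(npix, nd, nt))
  qc <- array(cu$qc[o] != 0, c(npix, nd, nt))
  cube <- structure(list(lst = lst, qc = qc, times = times,
                         lon = domain$lon), class = "vt_cube")
  da <- data.table::fread(fp("daily"), data.table = FALSE)
  need(da, c("pixel", "day", "fvc", "theta", "rs", "vpd"), "daily_env.csv")
  o <- order(da$day, da$pixel)
  daily <- list(fvc = matrix(da$fvc[o], npix), theta = matrix(da$theta[o], npix),
                rs = matrix(da$rs[o], npix), vpd = matrix(da$vpd[o], npix))
  pa <- data.table::fread(fp("panel"), data.table = FALSE)
  need(pa, c("pixel", "year", "ndvi", "lst", "p", "rs"), "annual_panel.csv")
  o <- order(pa$year, pa$pixel)
  years <- sort(unique(pa$year))
  panel <- list(ndvi = matrix(pa$ndvi[o], npix), lst = matrix(pa$lst[o], npix),
                p = matrix(pa$p[o], npix), rs = matrix(pa$rs[o], npix),
                years = years)
  tr <- jsonlite::read_json(fp("truth"), simplifyVector = TRUE)
  truth <- structure(list(
    beta_fvc_true = as.numeric(tr$beta_fvc_true),
    beta_albedo_true = as.numeric(tr$beta_albedo_true),
    beta_eff_true = as.numeric(tr$beta_eff_true),
    beta_ndvi_true = as.numeric(tr$beta_ndvi_true),
    ndvi_mean_true = as.numeric(tr$ndvi_mean_true),
    delta_lst_true = as.numeric(tr$delta_lst_true),
    effect_class_true = factor(tr$effect_class_true,
                               levels = c("cooling", "neutral", "warming")),
    r0_coef = as.numeric(tr$r0_coef)), class = "vt_truth")
  structure(list(domain = domain, fields = fields, cube = cube,
                 daily = daily, panel = panel, truth = truth,
                 config = list(seed = meta$seed, n_days = nd)),
            class = "vt_scene")
}

#' Write analysis outputs
#'
#' Writes the standard result files of an assessment: data-frame members
#' as CSV, scalar/list summaries as JSON.
#'
#' @param results an assessment object (`vt_assessment1`, `vt_mechanisms`,
#'   `vt_assessment3`) or a named list of data.frames/lists.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(results, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (inherits(results, "vt_assessment1")) {
    results <- list(bin_fits = results$bins,
                    pixel_class = data.frame(pixel = seq_along(results$class),
                                             class = as.character(results$class),
                                             beta_per_step = results$beta_per_step),
                    fractions = as.list(results$fractions))
  } else if (inherits(results, "vt_assessment3")) {
    results <- list(coverage = results$coverage,
                    delta_lst = data.frame(pixel = seq_along(results$delta),
                                           delta = results$delta,
                                           class = as.character(results$class)),
                    reduction = unclass(results$reduction))
  } else if (inherits(results, "vt_mechanisms")) {
    results <- list(albedo_bins = results$albedo_bins,
                    dissipation = data.frame(pixel = seq_along(results$dissipation$beta_eff),
                                             beta_eff = results$dissipation$beta_eff,
                                             n_increments = results$dissipation$n_increments),
                    contrasts = list(efficiency = unclass(results$contrast_eff),
                                     albedo = unclass(results$contrast_albedo)))
  }
  stopifnot(is.list(results), !is.null(names(results)))
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x))
      data.table::fwrite(x, file.path(path, paste0(nm, ".csv")))
    else
      jsonlite::write_json(x, file.path(path, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           force = TRUE)
  }
  invisible(path)
}
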