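test_that("dryland classification uses a strict threshold", {
  expect_equal(as.character(dryland_mask(c(400, 600))),
               c("dryland", "humid"))
  # a pixel exactly at the threshold is humid
  expect_equal(as.character(dryland_mask(500)), "humid")
  # sensitivity threshold 500 + 200
  expect_equal(as.character(dryland_mask(600, threshold = 700)), "dryland")
  expect_error(dryland_mask(c(-5, 100)), "finite and >= 0")
})

test_that("dryland/humid partition the vegetated set at every threshold", {
  set.seed(11)
  for (i in 1:10) {
    precip <- runif(200, 0, 1500)
    prev <- 0L
    for (thr in c(300, 500, 700, 900)) {
      m <- dryland_mask(precip, thr)
      expect_equal(sum(m == "dryland") + sum(m == "humid"), 200L)
      # raising the threshold never shrinks the dryland set
      expect_gte(sum(m == "dryland"), prev)
      prev <- sum(m == "dryland")
    }
  }
})

test_that("vegetated mask removes zero-FVC or barren pixels by mode", {
  expect_equal(vegetated_mask(fvc_mean = c(0, 0.3), mode = "fvc_zero"),
               c(FALSE, TRUE))
  expect_true(vegetated_mask(fvc_mean = 0.001, mode = "fvc_zero"))
  expect_equal(vegetated_mask(landcover = c(16L, 10L), mode = "igbp_bare"),
               c(FALSE, TRUE))
  expect_error(vegetated_mask(landcover = 42L, mode = "igbp_bare"),
               "unknown IGBP")
})

test_that("analysis configuration validates its invariants", {
  cfg <- analysis_config()
  expect_equal(cfg$theta_half_width, 0.0025)
  expect_equal(cfg$rs_half_width, 1.25)
  expect_equal(cfg$dryland_threshold, 500)
  expect_error(analysis_config(alpha_level = 1.5), "alpha_level")
  expect_error(analysis_config(morning_window = c(11, 7)), "time windows")
  expect_error(analysis_config(morning_window = c(7, 25)), "time windows")
})

test_that("configuration YAML round-trips and rejects unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("dryland_threshold: 700", "alpha_level: 0.01"), path)
  cfg <- read_config(path)
  expect_equal(cfg$dryland_threshold, 700)
  expect_equal(cfg$alpha_level, 0.01)
  expect_equal(cfg$rs_half_width, 1.25)
  writeLines("not_a_key: 1", path)
  expect_error(read_config(path), "unknown configuration keys")
})

test_that("grid domain rejects degenerate or out-of-range coordinates", {
  expect_error(grid_domain(numeric(0), numeric(0)), "empty domain")
  expect_error(grid_domain(95, 0), "lat")
  expect_error(grid_domain(0, 200), "lon")
  g <- grid_domain(c(0, 1), c(10, 10))
  expect_equal(g$pixel_id, 0:1)
})

test_that("scene bundles round-trip through the text format", {
  set.seed(99)
  for (seed in c(1, 7, 23)) {
    sc <- generate_scene(scene_config(nx = 2, ny = 2, n_days = 3,
                                      n_years = 4, seed = seed))
    dir <- withr::local_tempdir()
    write_scene(sc, dir)
    back <- read_scene(dir)
    expect_equal(back$fields$theta_mean, sc$fields$theta_mean, tolerance = 1e-12)
    expect_equal(as.data.frame(back$fields), as.data.frame(sc$fields),
                 tolerance = 1e-12)
    expect_equal(back$cube$lst, sc$cube$lst, tolerance = 1e-12)
    expect_identical(back$cube$qc, sc$cube$qc)
    expect_equal(back$cube$times, sc$cube$times)
    expect_equal(back$daily$fvc, sc$daily$fvc, tolerance = 1e-12)
    expect_equal(back$panel$lst, sc$panel$lst, tolerance = 1e-12)
    expect_equal(back$truth$beta_fvc_true, sc$truth$beta_fvc_true,
                 tolerance = 1e-12)
    expect_equal(as.character(back$truth$effect_class_true),
                 as.character(sc$truth$effect_class_true))
  }
})

test_that("scene reading fails descriptively on missing pieces", {
  sc <- generate_scene(scene_config(nx = 2, ny = 2, n_days = 2, seed = 5))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  file.remove(file.path(dir, "cube_lst.csv"))
  expect_error(read_scene(dir), "cube_lst.csv")

  dir2 <- withr::local_tempdir()
  write_scene(sc, dir2)
  cu <- read.csv(file.path(dir2, "cube_lst.csv"))
  cu$qc <- NULL
  write.csv(cu, file.path(dir2, "cube_lst.csv"), row.names = FALSE)
  expect_error(read_scene(dir2), "qc")

  dir3 <- withr::local_tempdir()
  write_scene(sc, dir3)
  meta <- jsonlite::read_json(file.path(dir3, "meta.json"), simplifyVector = TRUE)
  meta$n_pixels <- 0
  jsonlite::write_json(meta, file.path(dir3, "meta.json"), auto_unbox = TRUE)
  expect_error(read_scene(dir3), "empty domain")
})

test_that("assessment outputs are written as CSV/JSON tables", {
  sc <- exact_scene()
  a1 <- assess_fvc_effect(sc, small_cfg())
  dir <- withr::local_tempdir()
  write_outputs(a1, dir)
  expect_true(file.exists(file.path(dir, "bin_fits.csv")))
  expect_true(file.exists(file.path(dir, "fractions.json")))
  fr <- jsonlite::read_json(file.path(dir, "fractions.json"))
  expect_equal(sort(names(fr)), c("cooling", "neutral", "warming"))
})
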