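test_that("contour extraction recovers the membrane mid-surface", {
  p <- unit_params()
  g <- small_grid(64, 192, 32, -48, 48)
  R <- 15
  phi <- tanh_sphere(0, R, p, g)
  cl <- extract_contour(phi, g)
  expect_length(cl, 1)
  rad <- sqrt(cl[[1]]$r^2 + cl[[1]]$z^2)
  expect_lt(max(abs(rad - R)), g$dz)

  two <- compose_union(list(tanh_sphere(-20, 12, p, g),
                            tanh_sphere(20, 12, p, g)))
  expect_length(extract_contour(two, g), 2)
  # independent topology oracle: connected components of the phi > 0 set
  expect_equal(vesiclefusion:::count_regions(two), 2L)
  expect_equal(vesiclefusion:::count_regions(phi), 1L)

  expect_length(extract_contour(matrix(-1, g$nr, g$nz), g), 0)
})

test_that("shape metrics reproduce the reference two-vesicle geometry", {
  # the production setup: D = 146 nm spheres, eps = 5/6 nm, full grid
  p <- phys_params()
  cfg <- default_run_config()
  g <- build_grid(cfg$grid$nr, cfg$grid$nz, cfg$grid$r_max,
                  cfg$grid$z_min, cfg$grid$z_max)
  one <- tanh_sphere(0, 73, p, g)
  m1 <- shape_metrics(one, p, g)
  expect_rel_equal(m1$v, 1, 0.015)

  ts <- make_two_sphere_state(cfg$geometry$diameter, cfg$geometry$gap,
                              0, p, g)
  m2 <- shape_metrics(ts$phi, p, g)
  expect_rel_equal(m2$v, 1 / sqrt(2), 0.01)
  expect_rel_equal(m2$D_ve, sqrt(2) * 146, 0.01)   # ~206 nm
  expect_rel_equal(1 / m2$lambda, 247.5, 0.01)
})

test_that("snapshot container round-trips bit-identically", {
  set.seed(33)
  g <- small_grid(16, 24, 8, -6, 6)
  f1 <- matrix(rnorm(16 * 24), 16, 24)
  f2 <- matrix(runif(16 * 24), 16, 24)
  path <- tempfile(fileext = ".snap")
  write_snapshot(path, list(phi = f1, eta = f2),
                 meta = list(alpha = 0.25, note = "fixture"))
  back <- read_snapshot(path)
  expect_identical(back$fields$phi, f1)
  expect_identical(back$fields$eta, f2)
  expect_equal(back$meta$alpha, 0.25)
  unlink(path)
})

test_that("VTK export writes a well-formed rectilinear grid", {
  g <- small_grid(12, 16, 6, -4, 4)
  path <- tempfile(fileext = ".vtk")
  write_vtk(path, list(phi = matrix(0.5, 12, 16)), g)
  lines <- readLines(path)
  expect_equal(lines[4], "DATASET RECTILINEAR_GRID")
  expect_equal(lines[5], "DIMENSIONS 12 16 1")
  expect_true(any(grepl("SCALARS phi double 1", lines)))
  unlink(path)
})

test_that("configuration validation rejects bad inputs before compute", {
  cfg <- default_run_config()
  expect_equal(cfg$physics$eps, 5 / 6)
  expect_equal(cfg$geometry$diameter, 146)
  expect_equal(cfg$string$n_images, 100L)
  expect_silent(validate_run_config(cfg))

  bad <- cfg; bad$geometry$diameter <- -10
  expect_error(validate_run_config(bad), "diameter")
  bad <- cfg; bad$geometry$patch_fraction <- 1.5
  expect_error(validate_run_config(bad), "patch_fraction")
  bad <- cfg; bad$string$dt <- 0
  expect_error(validate_run_config(bad), "dt")

  # YAML round trip with overrides
  path <- tempfile(fileext = ".yaml")
  writeLines(c("physics:", "  k: 50.0", "string:", "  n_images: 20"), path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$physics$k, 50)
  expect_equal(cfg2$string$n_images, 20)
  expect_equal(cfg2$geometry$diameter, 146)
  writeLines(c("bogus:", "  x: 1"), path)
  expect_error(read_run_config(path), "unknown config block")
  unlink(path)
})

test_that("MEP CSV export has one row per image and dE[1] = 0", {
  p <- unit_params()
  g <- small_grid(24, 48, 12, -12, 12)
  cs <- constraint_set(A0 = 1, V0 = 1, P0 = NA)
  ea <- list(phi = tanh_sphere(0, 5, p, g), eta = matrix(-1, g$nr, g$nz))
  eb <- list(phi = tanh_sphere(0, 6, p, g), eta = matrix(-1, g$nr, g$nz))
  s <- init_string(ea, eb, 5, p, g)
  mep <- mep_profile(s, p, cs, g)
  path <- tempfile(fileext = ".csv")
  write_mep_csv(mep, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 5)
  expect_equal(df$dE[1], 0)
  unlink(path)
})

test_that("the fusion experiment driver runs end to end at smoke scale", {
  # tiny uniform-modulus configuration: exercises endpoint construction,
  # the staged string, evolution and every artifact writer (the physics
  # of this run is not asserted beyond basic sanity)
  cfg <- default_run_config()
  cfg$grid <- list(nr = 36L, nz = 156L, r_max = 24, z_min = -52,
                   z_max = 52)
  cfg$physics$eps <- 1
  cfg$geometry <- list(diameter = 32, gap = 3, patch_fraction = 0)
  cfg$string <- list(n_images = 6L, n_outer = 5L, n_inner = 2L,
                     dt = 2e-3, tol = 1e-4)
  out <- file.path(tempdir(), "fusion_smoke")
  cfg$output <- list(dir = out, snapshot_every = 5L)
  res <- run_fusion_experiment(cfg, write_artifacts = TRUE)
  expect_s3_class(res$mep, "mep_result")
  expect_equal(res$mep$dE[1], 0)
  expect_true(all(is.finite(res$mep$dE)))
  df <- read.csv(res$artifact_paths$mep_csv)
  expect_equal(nrow(df), 6)
  expect_equal(df$dE[1], 0)
  ext <- jsonlite::fromJSON(res$artifact_paths$extrema)
  expect_true(all(ext$barriers >= 0))
  expect_true(file.exists(res$artifact_paths$log))
  expect_true(any(grepl("config", readLines(res$artifact_paths$log))))
  snaps <- res$artifact_paths$snapshots
  expect_true(length(snaps) >= 2 && all(file.exists(snaps)))
  back <- read_snapshot(snaps[1])
  expect_identical(back$fields$phi, res$string$images[[1]]$phi)
  unlink(out, recursive = TRUE)
})
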