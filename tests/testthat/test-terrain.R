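# Analytic surfaces (planes, paraboloids, spikes) with hand-derivable
# derivatives are the oracles for the terrain operators.

plane <- function(n, fx = 0, fy = 0, c0 = 0, cell = 1) {
  # z = fx * x + fy * y with x east, y north
  r <- seep_raster(matrix(0, n, n), cell_size = cell)
  idx <- expand.grid(row = seq_len(n), col = seq_len(n))
  xy <- cell_centre(r, idx$row, idx$col)
  z <- matrix(0, n, n)
  z[cbind(idx$row, idx$col)] <- fx * xy$x + fy * xy$y + c0
  seep_raster(z, cell_size = cell)
}

test_that("slope and aspect recover analytic plane gradients", {
  flat <- plane(9)
  sa <- slope_aspect(flat)
  expect_equal(sa$slope$values[5, 5], 0)
  expect_true(is.na(sa$aspect$values[5, 5]))

  east <- plane(9, fx = 1)            # z = x: 45 degrees, facing east
  sa <- slope_aspect(east)
  expect_equal(sa$slope$values[5, 5], 45, tolerance = 1e-10)
  expect_equal(sa$aspect$values[5, 5], 90, tolerance = 1e-10)
  ne <- north_east_ness(sa$slope, sa$aspect)
  expect_equal(ne$eastness$values[5, 5], 1, tolerance = 1e-10)
  expect_equal(ne$northness$values[5, 5], 0, tolerance = 1e-10)

  north <- plane(9, fy = 1)           # z rises northward
  sa <- slope_aspect(north)
  expect_equal(sa$aspect$values[5, 5], 0, tolerance = 1e-10)
  expect_equal(north_east_ness(sa$slope, sa$aspect)$northness$values[5, 5], 1,
               tolerance = 1e-10)
  expect_error(slope_aspect(seep_raster(matrix(0, 2, 2))), "3x3")
})

test_that("edge and nodata cells are masked in slope output", {
  b <- plane(9, fx = 0.5)
  b$values[4, 4] <- NA
  sl <- slope_aspect(b)$slope$values
  expect_true(all(is.na(sl[1, ])) && all(is.na(sl[, 9])))
  expect_true(all(is.na(sl[3:5, 3:5])))  # neighbours of the nodata cell
  expect_false(is.na(sl[7, 7]))
})

test_that("northness and eastness stay on the unit circle", {
  scene <- small_scene(seed = 6)
  sl <- scene$preds$layers$slope$values
  n2e2 <- scene$preds$layers$northness$values^2 +
    scene$preds$layers$eastness$values^2
  pos <- !is.na(sl) & sl > 0
  expect_true(all(abs(n2e2[pos] - 1) < 1e-9))
})

test_that("BPI vanishes on affine surfaces and localizes a spike", {
  for (p in list(plane(41), plane(41, fx = 0.3, fy = -0.2, c0 = 5))) {
    b <- bpi(p, outer_radius = 5)$values
    interior <- b[10:32, 10:32]
    expect_lt(max(abs(interior)), 1e-9)
  }
  z <- matrix(0, 15, 15); z[8, 8] <- 10
  b <- bpi(seep_raster(z), outer_radius = 3, inner_radius = 1)$values
  expect_equal(b[8, 8], 10, tolerance = 1e-8)
  # 24 cells have centre distance in (1, 3]; each sees the spike once
  expect_equal(b[8, 10], -10 / 24, tolerance = 1e-8)
  # bowl centre sits below its annulus mean
  bowl <- seep_raster(matrix((rep(1:21, 21) - 11)^2 +
                               (rep(1:21, each = 21) - 11)^2, 21, 21) / 10)
  expect_lt(bpi(bowl, outer_radius = 4)$values[11, 11], 0)
  expect_error(bpi(plane(9), outer_radius = 1, inner_radius = 2), "outer_radius")
})

test_that("BPI respects the valid-fraction rule near edges", {
  p <- plane(21, fx = 0.1)
  b <- bpi(p, outer_radius = 8)$values
  expect_true(is.na(b[1, 1]))        # corner annulus mostly off-grid
  expect_false(is.na(b[11, 11]))
})

test_that("VRM is 0 on planes and matches the two-facet closed form", {
  for (p in list(plane(15), plane(15, fx = 1, fy = 0.5))) {
    sa <- slope_aspect(p)
    v <- vrm(sa$slope, sa$aspect, neighborhood = 5)$values
    expect_lt(max(abs(v[4:12, 4:12])), 1e-9)
  }
  # checkerboard of two opposing 45-degree facets: normals
  # (+-sin45, 0, cos45); with counts n1, n2 in the window,
  # VRM = 1 - sqrt(((n1-n2) sin45)^2 + (n cos45)^2) / n  ~ 1 - cos45
  n <- 21
  sl <- seep_raster(matrix(45, n, n))
  asp <- seep_raster(matrix(ifelse((outer(1:n, 1:n, "+")) %% 2 == 0, 90, 270), n, n))
  v <- vrm(sl, asp, neighborhood = 5)$values
  w <- 25; n1 <- 13; n2 <- 12
  expected <- 1 - sqrt(((n1 - n2) * sin(pi / 4))^2 + (w * cos(pi / 4))^2) / w
  expect_equal(v[11, 11], expected, tolerance = 1e-9)
  expect_equal(v[11, 11], 1 - cos(pi / 4), tolerance = 0.005)
})

test_that("VRM is invariant to elevation offsets and full aspect rotations", {
  scene <- small_scene(seed = 7)
  b <- scene$bathymetry
  sa <- slope_aspect(b)
  v1 <- vrm(sa$slope, sa$aspect, neighborhood = 9)$values
  b2 <- seep_raster(b$values + 123.4, b$cell_size, b$origin)
  sa2 <- slope_aspect(b2)
  v2 <- vrm(sa2$slope, sa2$aspect, neighborhood = 9)$values
  expect_equal(v1, v2, tolerance = 1e-9)
  asp3 <- sa$aspect; asp3$values <- (asp3$values + 360) %% 360
  v3 <- vrm(sa$slope, asp3, neighborhood = 9)$values
  expect_equal(v1, v3, tolerance = 1e-9)
})

test_that("curvature matches analytic second derivatives", {
  expect_equal(max(abs(curvature(plane(15, fx = 2, fy = -1, c0 = 3))$values[2:14, 2:14])),
               0, tolerance = 1e-9)
  # dome z = -(x^2 + y^2)/2: fitted a = b = -1/2, curvature -2(a+b) = +2
  n <- 21
  r <- seep_raster(matrix(0, n, n))
  idx <- expand.grid(row = 1:n, col = 1:n)
  xy <- cell_centre(r, idx$row, idx$col)
  dome <- matrix(0, n, n)
  dome[cbind(idx$row, idx$col)] <- -((xy$x - 10)^2 + (xy$y - 10)^2) / 2
  expect_equal(curvature(seep_raster(dome))$values[11, 11], 2, tolerance = 1e-9)
  # bowl is the mirror image
  expect_equal(curvature(seep_raster(-dome))$values[11, 11], -2, tolerance = 1e-9)
  # ridge z = -x^2: a = -1, b = 0, curvature +2
  ridge <- matrix(0, n, n)
  ridge[cbind(idx$row, idx$col)] <- -(xy$x - 10)^2
  expect_equal(curvature(seep_raster(ridge))$values[11, 11], 2, tolerance = 1e-9)
})

test_that("the default predictor set has 11 aligned layers and a union mask", {
  scene <- small_scene(seed = 1)
  preds <- scene$preds
  expect_named(preds$layers,
               c("slope", "northness", "eastness", "bpi_5", "bpi_15", "vrm",
                 "curvature", "d_carbonate", "d_mats", "d_mussels",
                 "d_tubeworms"))
  expect_equal(length(preds$layers), 11)
  # union mask: a cell NA in any layer is invalid
  na_any <- Reduce(`|`, lapply(preds$layers, function(l) is.na(l$values)))
  expect_identical(preds$valid, !na_any)
  # extraction blanks points on invalid cells
  bad_rc <- which(!preds$valid, arr.ind = TRUE)[1, ]
  xy <- cell_centre(preds$layers[[1]], bad_rc[1], bad_rc[2])
  row <- predictors_at(preds, xy$x, xy$y)
  expect_true(all(is.na(row)))
})

test_that("predictor rasters round-trip bit-exactly through ASCII grids", {
  scene <- small_scene(seed = 2)
  dir <- withr::local_tempdir()
  write_predictors(scene$preds, dir)
  for (n in c("slope", "d_carbonate")) {
    r2 <- read_asc(file.path(dir, paste0(n, ".asc")))
    expect_equal(r2$values, scene$preds$layers[[n]]$values, tolerance = 0)
  }
  expect_true(file.exists(file.path(dir, "layers.json")))
})
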