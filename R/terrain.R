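# Bathymetry-derived predictor layers: Horn slope/aspect, bathymetric
# position index (BPI) at metric scales, vector ruggedness (VRM), total
# curvature from a local quadratic fit, and distance-to-feature layers.

# Sum of `m` over a kernel footprint via FFT convolution; `m` must be
# NA-free (pre-multiply by the validity mask). Returns a matrix of sums of
# the neighbours selected by `kernel` (odd-dimensioned 0/1 matrix centred
# on the target cell); off-grid neighbours contribute 0.
.kernel_sum <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- m
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- kernel
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  ctr <- c((kr + 1L) %/% 2L, (kc + 1L) %/% 2L)
  conv[ctr[1] + seq_len(nr) - 1L, ctr[2] + seq_len(nc) - 1L]
}

# 3x3 neighbour matrices as shifted copies (NA off-grid), listed row-major
# z1..z9 with z1 = NW, z2 = N, ..., z5 = centre, ..., z9 = SE.
.shift9 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(NA_real_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- vector("list", 9L)
  k <- 0L
  for (di in 0:2) for (dj in 0:2) {
    k <- k + 1L
    out[[k]] <- pad[di + seq_len(nr), dj + seq_len(nc)]
  }
  out
}

#' Slope and aspect by Horn's method
#'
#' Horn's 3x3 weighted finite differences. Slope is degrees from horizontal.
#' Aspect is the compass direction of steepest ascent, degrees clockwise
#' from grid north, defined only where slope > 0; a plane rising eastward
#' has aspect 90. Cells with any nodata/off-grid neighbour are nodata.
#'
#' @param bathy bathymetry [seep_raster] (>= 3x3).
#' @return list of two [seep_raster]s: `slope` (degrees), `aspect` (degrees,
#'   `NA` where flat or nodata).
#' @export
slope_aspect <- function(bathy) {
  stopifnot(inherits(bathy, "seep_raster"))
  if (any(dim(bathy$values) < 3L))
    stop("grid must be at least 3x3", call. = FALSE)
  z <- .shift9(bathy$values)
  cs <- bathy$cell_size
  # east and north derivatives (z indices: 1 2 3 / 4 5 6 / 7 8 9, row 1 north)
  dzdx <- ((z[[3]] + 2 * z[[6]] + z[[9]]) - (z[[1]] + 2 * z[[4]] + z[[7]])) / (8 * cs)
  dzdy <- ((z[[1]] + 2 * z[[2]] + z[[3]]) - (z[[7]] + 2 * z[[8]] + z[[9]])) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(dzdx, dzdy) * 180 / pi) %% 360
  # Horn's stencil skips the centre cell; a nodata cell is still nodata
  slope[is.na(bathy$values)] <- NA_real_
  aspect[is.na(bathy$values)] <- NA_real_
  aspect[!is.na(slope) & slope == 0] <- NA_real_
  list(slope = seep_raster(slope, cs, bathy$origin),
       aspect = seep_raster(aspect, cs, bathy$origin))
}

#' Northness and eastness from aspect
#'
#' cos(aspect) and sin(aspect), decomposing the circular aspect into two
#' linear predictors; flat cells (undefined aspect but valid slope) get 0 in
#' both, keeping the layers defined everywhere the slope is.
#'
#' @param slope,aspect rasters from [slope_aspect()].
#' @return list of [seep_raster]s `northness`, `eastness`, each in \[-1, 1\].
#' @export
north_east_ness <- function(slope, aspect) {
  assert_aligned(slope, aspect)
  a <- aspect$values * pi / 180
  n <- cos(a); e <- sin(a)
  flat <- !is.na(slope$values) & is.na(aspect$values)
  n[flat] <- 0; e[flat] <- 0
  n[is.na(slope$values)] <- NA_real_; e[is.na(slope$values)] <- NA_real_
  list(northness = seep_raster(n, slope$cell_size, slope$origin),
       eastness = seep_raster(e, slope$cell_size, slope$origin))
}

#' Bathymetric position index
#'
#' Elevation of a cell minus the mean elevation over the annulus of cells
#' whose centre distance d satisfies `inner_radius < d <= outer_radius`
#' (metres). Positive on crests, negative in depressions, 0 on any affine
#' surface. Cells where fewer than `min_valid_frac` of the annulus cells are
#' valid (on-grid and not nodata) are nodata.
#'
#' @param bathy bathymetry [seep_raster].
#' @param outer_radius outer annulus radius, metres.
#' @param inner_radius inner radius, metres; default one cell, so the
#'   annulus is a punctured disc.
#' @param min_valid_frac minimum valid fraction of the annulus (default 0.5).
#' @return a [seep_raster] of BPI values, metres.
#' @export
bpi <- function(bathy, outer_radius, inner_radius = bathy$cell_size,
                min_valid_frac = 0.5) {
  stopifnot(inherits(bathy, "seep_raster"))
  if (!(outer_radius > inner_radius) || inner_radius < 0)
    stop("need outer_radius > inner_radius >= 0", call. = FALSE)
  cs <- bathy$cell_size
  k <- floor(outer_radius / cs)
  off <- seq(-k, k)
  d <- sqrt(outer(off^2, off^2, "+")) * cs
  kernel <- (d > inner_radius & d <= outer_radius) * 1
  if (sum(kernel) == 0)
    stop("annulus contains no cells at this cell size", call. = FALSE)
  valid <- !is.na(bathy$values)
  zv <- bathy$values; zv[!valid] <- 0
  s <- .kernel_sum(zv, kernel)
  n <- .kernel_sum(valid * 1, kernel)
  out <- bathy$values - s / n
  out[n < min_valid_frac * sum(kernel)] <- NA_real_
  out[!valid] <- NA_real_
  seep_raster(out, cs, bathy$origin)
}

#' Vector ruggedness measure
#'
#' Per-cell unit surface normals built from slope and aspect are summed over
#' a square metric neighbourhood; VRM = 1 - |resultant| / n_valid. 0 on any
#' plane (all normals parallel), approaching 1 for maximally rough terrain.
#' Flat cells contribute the vertical normal. Cells with no valid neighbour
#' are nodata.
#'
#' @param slope,aspect rasters from [slope_aspect()].
#' @param neighborhood square window edge, metres (default 25).
#' @return a [seep_raster] with values in \[0, 1\].
#' @export
vrm <- function(slope, aspect, neighborhood = 25) {
  assert_aligned(slope, aspect)
  cs <- slope$cell_size
  w <- max(3L, floor(neighborhood / cs))
  if (w %% 2L == 0L) w <- w - 1L  # odd window centred on the cell
  kernel <- matrix(1, w, w)
  sl <- slope$values * pi / 180
  as_ <- aspect$values * pi / 180
  flat <- !is.na(slope$values) & is.na(aspect$values)
  as_[flat] <- 0
  valid <- !is.na(sl) & (!is.na(as_) | flat)
  nx <- sin(sl) * sin(as_); ny <- sin(sl) * cos(as_); nz <- cos(sl)
  nx[!valid] <- 0; ny[!valid] <- 0; nz[!valid] <- 0
  sx <- .kernel_sum(nx, kernel); sy <- .kernel_sum(ny, kernel)
  sz <- .kernel_sum(nz, kernel); n <- .kernel_sum(valid * 1, kernel)
  out <- 1 - sqrt(sx^2 + sy^2 + sz^2) / n
  out[n == 0] <- NA_real_
  out[!valid] <- NA_real_
  out <- pmin(pmax(out, 0), 1)
  seep_raster(out, cs, slope$origin)
}

# Least-squares quadratic fit coefficients on the 3x3 stencil, as 9-weight
# kernels. Model z = a x^2 + b y^2 + c xy + d x + e y + f, x east, y north,
# offsets in metres. Returns the 6x9 pseudoinverse rows.
.quad_stencil <- function(cs) {
  # .shift9 lists k with di (row shift) outer, dj (col shift) inner:
  # di = (k-1) %/% 3, dj = (k-1) %% 3; x = (dj-1)*cs (east), y = (1-di)*cs (north)
  dj <- (seq_len(9) - 1) %% 3
  di <- (seq_len(9) - 1) %/% 3
  x <- (dj - 1) * cs; y <- (1 - di) * cs
  X <- cbind(x^2, y^2, x * y, x, y, 1)
  solve(crossprod(X), t(X))
}

#' Total curvature from a local quadratic fit
#'
#' A quadratic surface `z = a x^2 + b y^2 + c xy + d x + e y + f` is fitted
#' by least squares to each 3x3 window; curvature is `-2 (a + b)` per metre,
#' so convex-up (dome) cells are positive, concave (bowl) cells negative and
#' any plane is 0. Cells with any nodata neighbour are nodata.
#'
#' @param bathy bathymetry [seep_raster] (>= 3x3).
#' @return a [seep_raster] of curvature (1/metres).
#' @export
curvature <- function(bathy) {
  stopifnot(inherits(bathy, "seep_raster"))
  if (any(dim(bathy$values) < 3L))
    stop("grid must be at least 3x3", call. = FALSE)
  z <- .shift9(bathy$values)
  M <- .quad_stencil(bathy$cell_size)
  a <- 0; b <- 0
  for (k in seq_len(9)) {
    a <- a + M[1, k] * z[[k]]
    b <- b + M[2, k] * z[[k]]
  }
  out <- -2 * (a + b)
  out[is.na(bathy$values)] <- NA_real_
  seep_raster(out, bathy$cell_size, bathy$origin)
}

#' Derive the full terrain predictor stack
#'
#' @param bathy bathymetry [seep_raster].
#' @param bpi_scales outer radii for the two BPI layers, metres.
#' @param vrm_window VRM neighbourhood edge, metres.
#' @return named list of [seep_raster]s: `slope`, `northness`, `eastness`,
#'   `bpi_<s>` for each scale, `vrm`, `curvature`.
#' @export
terrain_stack <- function(bathy, bpi_scales = c(10, 100), vrm_window = 25) {
  sa <- slope_aspect(bathy)
  ne <- north_east_ness(sa$slope, sa$aspect)
  out <- list(slope = sa$slope, northness = ne$northness,
              eastness = ne$eastness)
  for (s in bpi_scales)
    out[[sprintf("bpi_%g", s)]] <- bpi(bathy, outer_radius = s)
  out$vrm <- vrm(sa$slope, sa$aspect, neighborhood = vrm_window)
  out$curvature <- curvature(bathy)
  out
}

#' Distance layers to carbonate and biogenic indicators
#'
#' @param features feature list from [place_features()] (binary rasters
#'   `carbonate`, `mats`, `mussels`, `tubeworms`).
#' @return named list of [seep_raster]s `d_carbonate`, `d_mats`,
#'   `d_mussels`, `d_tubeworms`, metres.
#' @export
distance_layers <- function(features) {
  nm <- c(carbonate = "d_carbonate", mats = "d_mats",
          mussels = "d_mussels", tubeworms = "d_tubeworms")
  out <- list()
  for (f in names(nm)) out[[nm[[f]]]] <- distance_to(features[[f]])
  out
}

#' Assemble the named, ordered predictor set
#'
#' Combines the terrain stack and distance layers into one aligned predictor
#' list (default 11 layers) with the union nodata mask: a cell that is
#' nodata in any layer is excluded from all downstream sampling.
#'
#' @param stack terrain list from [terrain_stack()].
#' @param dists distance list from [distance_layers()].
#' @return object of class `predictor_set`: list with `layers` (named list
#'   of rasters), `valid` (logical matrix), and per-layer `meta`.
#' @export
assemble_predictors <- function(stack, dists) {
  layers <- c(stack, dists)
  ref <- layers[[1]]
  for (l in layers) assert_aligned(ref, l)
  valid <- Reduce(`&`, lapply(layers, function(l) !is.na(l$values)))
  meta <- data.frame(
    name = names(layers),
    units = vapply(names(layers), function(n) {
      if (n == "slope") "degrees"
      else if (n %in% c("northness", "eastness", "vrm")) "dimensionless"
      else if (n == "curvature") "1/m" else "m"
    }, ""),
    stringsAsFactors = FALSE)
  structure(list(layers = layers, valid = valid, meta = meta,
                 cell_size = ref$cell_size, origin = ref$origin),
            class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("<predictor_set> %d layers on %d x %d grid (%d valid cells)\n",
              length(x$layers), nrow(x$valid), ncol(x$valid), sum(x$valid)))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Extract predictor values at point locations
#'
#' @param preds a `predictor_set`.
#' @param x,y point coordinates, metres.
#' @return data.frame, one column per predictor; rows on invalid or
#'   out-of-extent cells are all-`NA`.
#' @export
predictors_at <- function(preds, x, y) {
  stopifnot(inherits(preds, "predictor_set"))
  ref <- preds$layers[[1]]
  rc <- xy_to_cell(ref, x, y)
  idx <- cbind(rc$row, rc$col)
  out <- lapply(preds$layers, function(l) {
    v <- rep(NA_real_, length(x))
    ok <- !is.na(rc$row)
    v[ok] <- l$values[idx[ok, , drop = FALSE]]
    v
  })
  df <- as.data.frame(out)
  # rows whose cell fails the union mask are blanked entirely
  bad <- rep(FALSE, length(x))
  ok <- which(!is.na(rc$row))
  bad[ok] <- !preds$valid[idx[ok, , drop = FALSE]]
  df[bad, ] <- NA_real_
  df
}

#' Write all predictor layers as ESRI ASCII grids with a JSON sidecar
#'
#' @param preds a `predictor_set`.
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_predictors <- function(preds, dir) {
  stopifnot(inherits(preds, "predictor_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (n in names(preds$layers)) {
    p <- file.path(dir, paste0(n, ".asc"))
    write_asc(preds$layers[[n]], p)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, "layers.json")
  jsonlite::write_json(preds$meta, meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}
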