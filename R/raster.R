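#' Gridded raster layers on a local metric grid
#'
#' `seep_raster` is the package's container for single-band gridded data: a
#' numeric matrix (row 1 is the northern row, column 1 the western column)
#' plus a cell size in metres and the (x, y) coordinate of the outer corner
#' of the upper-left cell. `NA` cells are nodata. All layers derived from a
#' bathymetry grid share its geometry, so raster algebra is plain matrix
#' algebra after an alignment check.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, (x, y) of the upper-left cell's outer
#'   (north-west) corner. Defaults to `(0, nrow * cell_size)` so the
#'   lower-left corner of the grid sits at (0, 0).
#'
#' @return an object of class `seep_raster`.
#' @export
seep_raster <- function(values, cell_size = 1,
                        origin = c(0, nrow(values) * cell_size)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 2 || anyNA(origin))
    stop("`origin` must be (x, y) of the upper-left corner", call. = FALSE)
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "seep_raster")
}

#' @export
print.seep_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<seep_raster> %d rows x %d cols, cell %.3g m, origin (%.6g, %.6g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.seep_raster <- function(x) dim(x$values)

#' Extent of a raster
#'
#' @param r a [seep_raster].
#' @return named numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @export
raster_extent <- function(r) {
  stopifnot(inherits(r, "seep_raster"))
  d <- dim(r$values)
  c(xmin = r$origin[1], ymin = r$origin[2] - d[1] * r$cell_size,
    xmax = r$origin[1] + d[2] * r$cell_size, ymax = r$origin[2])
}

#' Cell-centre coordinates
#'
#' @param r a [seep_raster].
#' @param row,col 1-based indices (row 1 = north).
#' @return data.frame with columns `x`, `y` (metres).
#' @export
cell_centre <- function(r, row, col) {
  stopifnot(inherits(r, "seep_raster"))
  data.frame(x = r$origin[1] + (col - 0.5) * r$cell_size,
             y = r$origin[2] - (row - 0.5) * r$cell_size)
}

#' Map point coordinates to grid cells
#'
#' Cells are half-open, lower-left-closed: a point on a shared vertical edge
#' belongs to the cell on the east of it, one on a shared horizontal edge to
#' the cell above (whose ymin it is). Points outside the extent get `NA`.
#'
#' @param r a [seep_raster].
#' @param x,y point coordinates in metres.
#' @return data.frame with columns `row`, `col` (`NA` outside the extent).
#' @export
xy_to_cell <- function(r, x, y) {
  ext <- raster_extent(r)
  d <- dim(r$values)
  col <- floor((x - ext["xmin"]) / r$cell_size) + 1
  row <- d[1] - floor((y - ext["ymin"]) / r$cell_size)
  bad <- x < ext["xmin"] | x >= ext["xmax"] | y < ext["ymin"] | y >= ext["ymax"]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Check that two rasters share the same grid
#'
#' @param a,b [seep_raster] objects.
#' @param tol tolerance on origin/cell size comparison, metres.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
assert_aligned <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "seep_raster"), inherits(b, "seep_raster"))
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$cell_size - b$cell_size) > tol ||
      any(abs(a$origin - b$origin) > tol))
    stop("rasters are not aligned (grid, extent or cell size differ)",
         call. = FALSE)
  invisible(TRUE)
}

# --- ESRI ASCII grid I/O ------------------------------------------------
# Plain-text interchange format: 6-line header then rows north to south.

#' Write a raster as an ESRI ASCII grid
#'
#' @param r a [seep_raster].
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "seep_raster"))
  ext <- raster_extent(r)
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.10g", ext["xmin"]),
               sprintf("yllcorner %.10g", ext["ymin"]),
               sprintf("cellsize %.10g", r$cell_size),
               sprintf("NODATA_value %.10g", nodata)), con)
  # full precision so a round trip is value-exact
  write.table(format(v, digits = 17, trim = TRUE, scientific = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return a [seep_raster]; nodata cells become `NA`.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "[[:space:]]+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  for (k in c("ncols", "nrows", "cellsize"))
    if (!k %in% key) stop("malformed ASCII grid header: missing ", k, call. = FALSE)
  body <- scan(path, skip = 6, quiet = TRUE)
  nr <- val["nrows"]; nc <- val["ncols"]
  if (length(body) != nr * nc)
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if ("nodata_value" %in% key) m[m == val["nodata_value"]] <- NA
  seep_raster(m, cell_size = val[["cellsize"]],
              origin = c(val[["xllcorner"]],
                         val[["yllcorner"]] + nr * val[["cellsize"]]))
}

# --- exact Euclidean distance transform ---------------------------------

# 1-D squared-distance transform (lower envelope of parabolas).
# f: vector of squared costs; returns min_q' (q - q')^2 + f(q').
.dt1 <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance to the nearest feature cell
#'
#' Distance from every cell centre to the nearest centre of a feature cell
#' (cells where the input is 1/`TRUE`), in metres. Exact (two-pass
#' separable squared-distance transform), so it agrees with brute-force
#' nearest-feature search to floating-point precision.
#'
#' @param feature a [seep_raster] whose nonzero, non-`NA` cells are features,
#'   or a logical/numeric matrix (then `cell_size` is used).
#' @param cell_size cell size in metres when `feature` is a bare matrix.
#' @return a [seep_raster] of distances (metres); 0 on feature cells.
#'   Nodata cells of the input still receive a distance (distance is a
#'   property of the geometry), but callers normally mask them afterwards.
#' @export
distance_to <- function(feature, cell_size = 1) {
  if (inherits(feature, "seep_raster")) {
    m <- feature$values
    cs <- feature$cell_size
    org <- feature$origin
  } else {
    m <- feature
    cs <- cell_size
    org <- c(0, nrow(m) * cs)
  }
  on_cells <- !is.na(m) & m != 0
  if (!any(on_cells)) stop("feature raster has no feature cells", call. = FALSE)
  big <- 1e15  # finite sentinel keeps the envelope arithmetic NaN-free
  f <- matrix(big, nrow(m), ncol(m))
  f[on_cells] <- 0
  for (j in seq_len(ncol(f))) f[, j] <- .dt1(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- .dt1(f[i, ])
  seep_raster(sqrt(f) * cs, cell_size = cs, origin = org)
}

# Binary dilation of a feature raster by a metric radius, via the EDT.
.dilate <- function(feature, radius_m) {
  d <- distance_to(feature)
  out <- feature
  out$values <- (d$values <= radius_m) * 1
  out
}
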