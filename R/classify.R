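# Fishnet-based active/transition habitat classification of occurrence
# points and the nearest-seep-indicator distance analysis. A 5 m x 5 m grid
# partitions the site; a cell holding at least one living seep indicator
# (mats, mussels, tubeworms) is "active" seepage, a cell with carbonate but
# no indicator is a "transition" zone, anything else is "none".

#' Build a fishnet grid over an extent
#'
#' Half-open square cells tile the extent, anchored at its lower-left
#' corner; partial cells at the top/right edges are retained and flagged.
#' Points on shared edges fall in exactly one cell (lower-left-closed).
#'
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in metres, or a
#'   [seep_raster] whose extent is used.
#' @param cell fishnet cell edge, metres (default 5).
#' @return object of class `fishnet`: data.frame of cells (`cell_id`, `row`,
#'   `col`, bounds, `partial`) with the extent and cell size as attributes.
#'   Rows count from the top (north), columns from the west.
#' @export
build_fishnet <- function(extent, cell = 5) {
  if (inherits(extent, "seep_raster")) extent <- raster_extent(extent)
  if (cell <= 0) stop("fishnet cell size must be > 0", call. = FALSE)
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  if (w <= 0 || h <= 0) stop("extent must have positive area", call. = FALSE)
  ncx <- ceiling(w / cell); nry <- ceiling(h / cell)
  g <- expand.grid(col = seq_len(ncx), row = seq_len(nry))
  xmin <- extent[1] + (g$col - 1) * cell
  ymax <- extent[4] - (g$row - 1) * cell
  cells <- data.frame(
    cell_id = (g$row - 1L) * ncx + g$col,
    row = g$row, col = g$col,
    xmin = xmin, ymin = pmax(ymax - cell, extent[2]),
    xmax = pmin(xmin + cell, extent[3]), ymax = ymax)
  cells$partial <- (cells$xmax - cells$xmin < cell - 1e-12) |
    (cells$ymax - cells$ymin < cell - 1e-12)
  structure(cells[order(cells$cell_id), ],
            extent = unname(extent), cell = cell,
            nrow_cells = nry, ncol_cells = ncx,
            class = c("fishnet", "data.frame"))
}

# fishnet cell id for points; NA outside the extent
.fishnet_cell_id <- function(net, x, y) {
  ext <- attr(net, "extent"); cell <- attr(net, "cell")
  ncx <- attr(net, "ncol_cells"); nry <- attr(net, "nrow_cells")
  col <- floor((x - ext[1]) / cell) + 1
  row <- nry - floor((y - ext[2]) / cell)
  bad <- x < ext[1] | x >= ext[3] | y < ext[2] | y >= ext[4]
  # points in partial edge cells: clamp indices produced by the full-cell
  # arithmetic (top row is flush by construction; right edge can overflow
  # only for x >= xmax which `bad` already removes)
  id <- (row - 1) * ncx + col
  id[bad] <- NA_integer_
  as.integer(id)
}

#' Classify fishnet cells as active, transition or none
#'
#' A cell is `active` if it contains at least one indicator cell centre
#' (bacterial mats, mussels or tubeworms), `transition` if it contains
#' carbonate but no indicator, else `none`. Provenance records which
#' indicator classes triggered "active".
#'
#' @param net a [build_fishnet()] grid.
#' @param features feature list (binary rasters `carbonate`, `mats`,
#'   `mussels`, `tubeworms`) aligned to the extent the fishnet was built on.
#' @return object of class `cell_classification`: the fishnet data.frame
#'   with `label` and `provenance` columns.
#' @export
classify_cells <- function(net, features) {
  stopifnot(inherits(net, "fishnet"))
  ref <- features$carbonate
  ext <- attr(net, "extent")
  rext <- raster_extent(ref)
  if (any(abs(rext - ext) > 1e-9))
    stop("feature rasters are not aligned to the fishnet extent", call. = FALSE)
  hit <- function(r) {
    on <- which(!is.na(r$values) & r$values != 0, arr.ind = TRUE)
    if (nrow(on) == 0) return(integer(0))
    xy <- cell_centre(r, on[, 1], on[, 2])
    unique(.fishnet_cell_id(net, xy$x, xy$y))
  }
  ids <- list(carbonate = hit(features$carbonate), mats = hit(features$mats),
              mussels = hit(features$mussels), tubeworms = hit(features$tubeworms))
  lab <- rep("none", nrow(net))
  prov <- rep("", nrow(net))
  for (cls in c("mats", "mussels", "tubeworms")) {
    m <- net$cell_id %in% ids[[cls]]
    lab[m] <- "active"
    prov[m] <- ifelse(prov[m] == "", cls, paste(prov[m], cls, sep = "+"))
  }
  trans <- lab == "none" & net$cell_id %in% ids$carbonate
  lab[trans] <- "transition"
  out <- net
  out$label <- lab
  out$provenance <- prov
  class(out) <- c("cell_classification", class(net))
  out
}

#' Label occurrences by their fishnet cell
#'
#' Each occurrence inherits its cell's label: `active` occurrences are
#' seep-associated, `transition` occurrences carbonate-only associated;
#' occurrences in `none` cells are flagged unclassified and excluded from
#' percentage denominators.
#'
#' @param occ data.frame with columns `x`, `y` (and optionally `image_id`).
#' @param cells a [classify_cells()] result.
#' @return `occ` with `cell_id` and `label` columns added (`label` is
#'   `"none"` for unclassified points, `NA` outside the extent).
#' @export
classify_occurrences <- function(occ, cells) {
  stopifnot(inherits(cells, "cell_classification"))
  id <- .fishnet_cell_id(cells, occ$x, occ$y)
  occ$cell_id <- id
  occ$label <- cells$label[match(id, cells$cell_id)]
  occ
}

#' Distance from each occurrence to the nearest seep indicator
#'
#' Minimum Euclidean distance from each occurrence point to any indicator
#' cell centre (mats, mussels or tubeworms), plus a per-class summary. If no
#' indicator cells exist, all distances are `NA` with a warning.
#'
#' @param occ occurrence data.frame with `x`, `y`, and (after
#'   [classify_occurrences()]) optionally `label`.
#' @param features feature raster list.
#' @return list with `distances` (numeric per occurrence, metres) and
#'   `summary` (a [distribution_summary()] data.frame if labels available).
#' @export
nearest_indicator_distance <- function(occ, features) {
  cent <- list()
  for (cls in c("mats", "mussels", "tubeworms")) {
    r <- features[[cls]]
    on <- which(!is.na(r$values) & r$values != 0, arr.ind = TRUE)
    if (nrow(on) > 0) cent[[cls]] <- cell_centre(r, on[, 1], on[, 2])
  }
  if (length(cent) == 0) {
    warning("no indicator cells: distances undefined")
    d <- rep(NA_real_, nrow(occ))
  } else {
    pts <- do.call(rbind, cent)
    d <- vapply(seq_len(nrow(occ)), function(i)
      sqrt(min((pts$x - occ$x[i])^2 + (pts$y - occ$y[i])^2)), 0)
  }
  res <- list(distances = d)
  if ("label" %in% names(occ)) res$summary <- distribution_summary(occ, d)
  res
}

#' Summarize the active/transition distribution of occurrences
#'
#' Counts and percentage of classified occurrences per habitat class, with
#' mean and sample (n-1) SD of nearest-indicator distance overall and per
#' class. Occurrences in `none` cells are excluded from the percentage
#' denominator and counted separately.
#'
#' @param occ labelled occurrences (from [classify_occurrences()]).
#' @param distances per-occurrence nearest-indicator distances, metres.
#' @return data.frame with one row per class (`active`, `transition`,
#'   `overall`, `unclassified`): `n`, `pct`, `mean_dist`, `sd_dist`.
#' @export
distribution_summary <- function(occ, distances) {
  stopifnot(nrow(occ) == length(distances))
  lab <- occ$label
  classified <- !is.na(lab) & lab %in% c("active", "transition")
  n_cl <- sum(classified)
  row <- function(name, sel) {
    d <- distances[sel]
    data.frame(class = name, n = sum(sel),
               pct = if (name %in% c("active", "transition") && n_cl > 0)
                 100 * sum(sel) / n_cl else NA_real_,
               mean_dist = if (any(sel)) mean(d, na.rm = TRUE) else NA_real_,
               sd_dist = if (sum(sel) > 1) stats::sd(d, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(row("active", classified & lab == "active"),
        row("transition", classified & lab == "transition"),
        row("overall", classified),
        row("unclassified", !classified))
}
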