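# Synthetic seep mound with known ground truth: bathymetry, carbonate and
# biogenic indicator features, a planted suitability surface, occurrence
# points and isotope samples. Every generator is a pure function of its
# configuration (including the seed).

# Run `expr` under a seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  force(seed)  # must draw from the caller's stream before we snapshot it
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of a synthetic seep-mound scene
#'
#' Defaults describe the study conditions every downstream stage is exercised
#' under: a 256 m x 256 m grid of 1 m cells holding a smooth carbonate mound
#' with metre-scale roughness, eight carbonate patches of which a fraction
#' host biogenic seep indicators (bacterial mats, bathymodiolin mussels,
#' vestimentiferan tubeworms).
#'
#' @param extent_cells integer pair (rows, cols), each >= 64.
#' @param cell_size cell edge, metres.
#' @param mound_height height of the central mound, metres.
#' @param noise_amplitude standard deviation of the correlated roughness, metres.
#' @param noise_correlation_length correlation length of the roughness, metres.
#' @param n_carbonate_patches number of carbonate patches.
#' @param patch_radius_range (min, max) patch radius, metres.
#' @param seep_fraction fraction of carbonate patches hosting indicators, in \[0, 1\].
#' @param rng_seed integer seed; the scene is a pure function of the config.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(extent_cells = c(256, 256), cell_size = 1,
                         mound_height = 20, noise_amplitude = 0.4,
                         noise_correlation_length = 8,
                         n_carbonate_patches = 8,
                         patch_radius_range = c(3, 8),
                         seep_fraction = 0.6, rng_seed = 1) {
  cfg <- list(extent_cells = as.integer(extent_cells), cell_size = cell_size,
              mound_height = mound_height, noise_amplitude = noise_amplitude,
              noise_correlation_length = noise_correlation_length,
              n_carbonate_patches = as.integer(n_carbonate_patches),
              patch_radius_range = patch_radius_range,
              seep_fraction = seep_fraction, rng_seed = as.integer(rng_seed))
  if (length(cfg$extent_cells) != 2 || any(cfg$extent_cells < 64))
    stop("extent_cells must be a pair of integers >= 64", call. = FALSE)
  if (cfg$cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  if (cfg$seep_fraction < 0 || cfg$seep_fraction > 1)
    stop("seep_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$n_carbonate_patches < 0)
    stop("n_carbonate_patches must be >= 0", call. = FALSE)
  if (length(cfg$patch_radius_range) != 2 ||
      any(cfg$patch_radius_range <= 0) ||
      diff(cfg$patch_radius_range) < 0)
    stop("patch_radius_range must be increasing positive (min, max)", call. = FALSE)
  if (cfg$noise_amplitude < 0) stop("noise_amplitude must be >= 0", call. = FALSE)
  class(cfg) <- "scene_config"
  cfg
}

# Stationary Gaussian random field, unit variance, via spectral filtering of
# white noise with a Gaussian transfer function of the given correlation
# length (in cells).
.gaussian_field <- function(nr, nc, corr_cells) {
  wn <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_cells <= 0) return(wn)
  fi <- c(seq(0, floor(nr / 2)), seq(-(ceiling(nr / 2) - 1), -1)) / nr
  fj <- c(seq(0, floor(nc / 2)), seq(-(ceiling(nc / 2) - 1), -1)) / nc
  k2 <- outer(fi^2, rep(1, nc)) + outer(rep(1, nr), fj^2)
  filt <- exp(-2 * pi^2 * corr_cells^2 * k2)
  z <- Re(stats::fft(stats::fft(wn) * filt, inverse = TRUE)) / (nr * nc)
  z / stats::sd(as.vector(z))
}

#' Generate the synthetic bathymetry grid
#'
#' A radially symmetric Gaussian mound rising `mound_height` metres from a
#' ~1000 m-deep seafloor, plus a spatially correlated Gaussian roughness
#' field of standard deviation `noise_amplitude`. Deterministic per seed.
#'
#' @param cfg a [scene_config].
#' @return a [seep_raster] of elevation (metres, negative down).
#' @export
generate_bathymetry <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  nr <- cfg$extent_cells[1]; nc <- cfg$extent_cells[2]
  cs <- cfg$cell_size
  r <- seep_raster(matrix(0, nr, nc), cell_size = cs)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  xy <- cell_centre(r, idx$row, idx$col)
  ext <- raster_extent(r)
  cx <- mean(ext[c("xmin", "xmax")]); cy <- mean(ext[c("ymin", "ymax")])
  sigma <- min(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"]) / 6
  mound <- cfg$mound_height * exp(-((xy$x - cx)^2 + (xy$y - cy)^2) / (2 * sigma^2))
  z <- matrix(-1000, nr, nc)
  z[cbind(idx$row, idx$col)] <- z[cbind(idx$row, idx$col)] + mound
  if (cfg$noise_amplitude > 0) {
    noise <- .with_seed(cfg$rng_seed,
                        .gaussian_field(nr, nc, cfg$noise_correlation_length / cs))
    z <- z + cfg$noise_amplitude * noise
  }
  seep_raster(z, cell_size = cs)
}

#' Place carbonate patches and biogenic seep indicators
#'
#' Carbonate patches are discs at random locations in the central portion of
#' the grid (kept away from the border so terrain windows around occurrences
#' stay on-grid). A fraction `seep_fraction` of patches are actively seeping:
#' each hosts small blobs of all three indicator classes (mats, mussels,
#' tubeworms), placed within 3 m of the carbonate footprint. The shared
#' patch geometry makes the three indicator distance layers strongly
#' correlated, as successive seep stages are in the field.
#'
#' @param bathy bathymetry [seep_raster] defining the grid.
#' @param cfg a [scene_config].
#' @return named list of binary [seep_raster]s:
#'   `carbonate`, `mats`, `mussels`, `tubeworms`.
#' @export
place_features <- function(bathy, cfg) {
  stopifnot(inherits(bathy, "seep_raster"), inherits(cfg, "scene_config"))
  if (cfg$n_carbonate_patches == 0 && cfg$seep_fraction > 0)
    stop("cannot host seep indicators with zero carbonate patches", call. = FALSE)
  nr <- nrow(bathy$values); nc <- ncol(bathy$values); cs <- bathy$cell_size
  blank <- function() seep_raster(matrix(0, nr, nc), cs, bathy$origin)
  out <- list(carbonate = blank(), mats = blank(),
              mussels = blank(), tubeworms = blank())
  if (cfg$n_carbonate_patches == 0) return(out)

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  disc <- function(r0, c0, radius_cells)
    (rows - r0)^2 + (cols - c0)^2 <= radius_cells^2

  .with_seed(cfg$rng_seed + 1L, {
    n <- cfg$n_carbonate_patches
    # patch centres within the inner 56% of each axis
    pr <- round(stats::runif(n, 0.22 * nr, 0.78 * nr))
    pc <- round(stats::runif(n, 0.22 * nc, 0.78 * nc))
    rad <- stats::runif(n, cfg$patch_radius_range[1], cfg$patch_radius_range[2]) / cs
    for (i in seq_len(n))
      out$carbonate$values[disc(pr[i], pc[i], rad[i])] <- 1
    n_seep <- if (cfg$seep_fraction > 0) max(1L, round(cfg$seep_fraction * n)) else 0L
    if (n_seep > 0) {
      halo <- .dilate(out$carbonate, 3 * cs)$values > 0
      classes <- c("mats", "mussels", "tubeworms")
      # each seep patch hosts a random subset of indicator classes (>= 1),
      # emulating successional stages: the distance layers come out strongly
      # but not perfectly correlated
      host <- matrix(stats::runif(n_seep * 3) < 0.7, n_seep, 3)
      for (i in seq_len(n_seep))
        if (!any(host[i, ])) host[i, sample.int(3, 1)] <- TRUE
      for (j in 1:3)
        if (!any(host[, j])) host[sample.int(n_seep, 1), j] <- TRUE
      for (i in seq_len(n_seep)) {
        for (j in which(host[i, ])) {
          ang <- stats::runif(1, 0, 2 * pi)
          off <- stats::runif(1, 0, rad[i])
          blob <- disc(pr[i] + off * sin(ang), pc[i] + off * cos(ang),
                       max(1.5, 0.25 * rad[i]))
          out[[classes[j]]]$values[blob & halo] <- 1
        }
      }
    }
  })
  out
}

#' Planted ("true") habitat suitability surface
#'
#' The known ground truth downstream models must recover:
#' `exp(-d_carb / decay_carbonate) * (0.5 + 0.5 * exp(-d_ind / decay_indicator))`,
#' clipped to \[0, 1\] — a sharp decay away from carbonate (2 m scale) times a
#' milder decay away from the nearest biogenic indicator (10 m scale). It
#' attains its maximum (1) exactly on carbonate cells that host an indicator.
#' With no indicator cells present the indicator factor is the constant 0.5.
#'
#' @param features feature list from [place_features()].
#' @param decay_carbonate e-folding scale of the carbonate term, metres.
#' @param decay_indicator e-folding scale of the indicator term, metres.
#' @return list with `surface` (a [seep_raster] in \[0, 1\]) and the two
#'   decay parameters echoed.
#' @export
true_suitability <- function(features, decay_carbonate = 2, decay_indicator = 10) {
  carb <- features$carbonate
  d_carb <- distance_to(carb)$values
  ind <- carb
  ind$values <- pmin(features$mats$values + features$mussels$values +
                       features$tubeworms$values, 1)
  d_ind <- if (any(ind$values > 0)) distance_to(ind)$values
           else matrix(Inf, nrow(carb$values), ncol(carb$values))
  s <- exp(-d_carb / decay_carbonate) * (0.5 + 0.5 * exp(-d_ind / decay_indicator))
  s <- pmin(pmax(s, 0), 1)
  list(surface = seep_raster(s, carb$cell_size, carb$origin),
       decay_carbonate = decay_carbonate, decay_indicator = decay_indicator)
}

#' Sample occurrence points from a suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability, and points are placed at cell centres — one occurrence per
#' grid cell, mirroring deduplication of presences on the analysis grid.
#'
#' @param suit a [seep_raster] of suitability (or the list from
#'   [true_suitability()]).
#' @param n number of occurrences (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y` (metres) and `image_id`.
#' @export
sample_occurrences <- function(suit, n = 155, seed = 1) {
  if (is.list(suit) && !inherits(suit, "seep_raster")) suit <- suit$surface
  stopifnot(inherits(suit, "seep_raster"), n >= 1)
  v <- as.vector(suit$values)
  ok <- which(!is.na(v) & v > 0)
  if (length(ok) < n)
    stop(sprintf("only %d cells with positive suitability; cannot sample %d",
                 length(ok), n), call. = FALSE)
  pick <- .with_seed(seed, sample(ok, n, replace = FALSE, prob = v[ok]))
  rc <- arrayInd(pick, dim(suit$values))
  xy <- cell_centre(suit, rc[, 1], rc[, 2])
  data.frame(x = xy$x, y = xy$y,
             image_id = sprintf("synthimg_%06d", pick),
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic isotope sampler
#'
#' Defaults are the two-group tissue values reported for the coral:
#' active-zone native delta13C -26.2 +/- 1.8 permil, transition-zone
#' -22.0 +/- 0.2 permil; delta15N 10.1 +/- 1.3 vs 10.7 +/- 0.2 permil; group
#' sizes 19 and 3. Incubation with 13C-labelled methane shifts delta13C of an
#' active-zone specimen by `uptake_shift` (+62 permil) with probability
#' `uptake_probability` (default 1/3, one responder among three incubated),
#' otherwise values drift by a small handling/turnover offset.
#'
#' @param n_active,n_transition group sizes.
#' @param mean_active_c13,sd_active_c13 native active-zone delta13C, permil.
#' @param mean_transition_c13,sd_transition_c13 native transition delta13C, permil.
#' @param mean_active_n15,sd_active_n15 native active-zone delta15N, permil.
#' @param mean_transition_n15,sd_transition_n15 native transition delta15N, permil.
#' @param uptake_probability probability an active specimen assimilates label.
#' @param uptake_shift delta13C shift of a label-assimilating specimen, permil.
#' @param drift_mean,drift_sd incubation drift for non-assimilating tissue, permil.
#' @param rng_seed integer seed.
#' @return an object of class `isotope_sim_config`.
#' @export
isotope_sim_config <- function(n_active = 19, n_transition = 3,
                               mean_active_c13 = -26.2, sd_active_c13 = 1.8,
                               mean_transition_c13 = -22.0, sd_transition_c13 = 0.2,
                               mean_active_n15 = 10.1, sd_active_n15 = 1.3,
                               mean_transition_n15 = 10.7, sd_transition_n15 = 0.2,
                               uptake_probability = 1 / 3, uptake_shift = 62,
                               drift_mean = -1.5, drift_sd = 1.0, rng_seed = 1) {
  cfg <- as.list(environment())
  cfg$n_active <- as.integer(n_active)
  cfg$n_transition <- as.integer(n_transition)
  if (cfg$n_active < 0 || cfg$n_transition < 0)
    stop("group sizes must be non-negative", call. = FALSE)
  sds <- c(sd_active_c13, sd_transition_c13, sd_active_n15, sd_transition_n15,
           drift_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (uptake_probability < 0 || uptake_probability > 1)
    stop("uptake_probability must be in [0, 1]", call. = FALSE)
  class(cfg) <- "isotope_sim_config"
  cfg
}

#' Simulate per-specimen isotope records
#'
#' Native values are drawn from the two group distributions; incubated
#' delta13C is native + `uptake_shift` for label-assimilating active-zone
#' specimens, otherwise native + drift; incubated delta15N is native plus a
#' small zero-mean drift.
#'
#' @param cfg an [isotope_sim_config].
#' @return data.frame of isotope records (one row per specimen) with columns
#'   `specimen_id`, `habitat`, `native_d13c`, `native_d15n`,
#'   `incubated_d13c`, `incubated_d15n`.
#' @export
generate_isotopes <- function(cfg = isotope_sim_config()) {
  stopifnot(inherits(cfg, "isotope_sim_config"))
  .with_seed(cfg$rng_seed, {
    na <- cfg$n_active; nt <- cfg$n_transition
    habitat <- c(rep("active", na), rep("transition", nt))
    d13 <- c(stats::rnorm(na, cfg$mean_active_c13, cfg$sd_active_c13),
             stats::rnorm(nt, cfg$mean_transition_c13, cfg$sd_transition_c13))
    d15 <- c(stats::rnorm(na, cfg$mean_active_n15, cfg$sd_active_n15),
             stats::rnorm(nt, cfg$mean_transition_n15, cfg$sd_transition_n15))
    uptake <- c(stats::runif(na) < cfg$uptake_probability, rep(FALSE, nt))
    drift <- stats::rnorm(na + nt, cfg$drift_mean, cfg$drift_sd)
    inc13 <- ifelse(uptake, d13 + cfg$uptake_shift, d13 + drift)
    inc15 <- d15 + stats::rnorm(na + nt, 0, cfg$drift_sd / 2)
    data.frame(specimen_id = sprintf("sim_%03d", seq_len(na + nt)),
               habitat = habitat, native_d13c = d13, native_d15n = d15,
               incubated_d13c = inc13, incubated_d15n = inc15,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper running bathymetry, feature placement, the planted
#' suitability surface and occurrence sampling with one configuration.
#'
#' @param cfg a [scene_config].
#' @param n_occurrences number of presence points to sample.
#' @return list with `config`, `bathymetry`, `features`, `suitability`
#'   (list from [true_suitability()]) and `occurrences`.
#' @export
simulate_scene <- function(cfg = scene_config(), n_occurrences = 155) {
  bathy <- generate_bathymetry(cfg)
  feats <- place_features(bathy, cfg)
  suit <- true_suitability(feats)
  occ <- sample_occurrences(suit$surface, n = n_occurrences,
                            seed = cfg$rng_seed + 2L)
  list(config = cfg, bathymetry = bathy, features = feats,
       suitability = suit, occurrences = occ)
}
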