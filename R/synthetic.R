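#' Synthetic-landscape scenario
#'
#' Parameter set for the synthetic generator, which emulates the structure
#' of the study system at desk scale: a 30 m grid over a 20-year study
#' period (Jan 2000 -- Dec 2019) with sub-monthly acquisitions, a bimodal
#' seasonal cycle (two rainy seasons), spatially clustered small grove
#' polygons (log-normal areas, median 0.285 ha), a weak background
#' greening trend, a grove greening effect that decays with distance and
#' vanishes beyond a finite spill-over range, observation noise, and
#' cloud- plus scan-stripe-style missingness.
#'
#' Effect sizes are in NDVI units per decade. The grove effect enters as a
#' trend (a greening ramp starting at `effect_start`), not a level shift,
#' so it survives decycling and is visible to the rank trend statistic.
#' `decay_length_m` sets the exponential shape of the decay;
#' `spill_range_m` is the planted spill-over length -- the distance beyond
#' which the grove effect is exactly zero (a pure exponential never
#' reaches zero, so it has no finite spill-over length to recover).
#'
#' @param n_rows,n_cols,pixel_size,crs_id grid layout (defaults
#'   200 x 200 cells of 30 m).
#' @param period study period.
#' @param cadence `"8day"` (46 nominal acquisitions per year) or
#'   `"monthly"` (one per month; the cheap desk-scale equivalent).
#' @param n_grove_clusters,groves_per_cluster,cluster_radius_m clustered
#'   grove placement.
#' @param grove_area_meanlog,grove_area_sdlog log-normal grove areas (ha);
#'   the default meanlog gives median 0.285 ha.
#' @param baseline mean NDVI level.
#' @param season_amp,season_doy,season_sd two seasonal Gaussian bumps:
#'   amplitudes, peak days-of-year (~April and ~November rains) and
#'   widths (days).
#' @param background_slope_mean,background_slope_sd per-pixel background
#'   trend (NDVI/decade), normal across pixels.
#' @param grove_effect_size greening trend at the grove itself
#'   (NDVI/decade).
#' @param decay_length_m exponential decay length of the effect (m).
#' @param spill_range_m planted spill-over length (m); effect is zero
#'   beyond it.
#' @param effect_start date the grove greening ramp starts.
#' @param noise_sd Gaussian observation noise (NDVI units).
#' @param missing_rate random missingness per observation.
#' @param stripe_period,stripe_width,stripe_start periodic missing column
#'   stripes (scan-line emulation) applied to acquisitions after
#'   `stripe_start`.
#' @param non_agri_fraction fraction of the scene masked non-agricultural.
#' @param seed RNG seed; a fixed seed reproduces the scene exactly.
#' @return an object of class `scenario`.
#' @export
scenario <- function(n_rows = 200, n_cols = 200, pixel_size = 30,
                     crs_id = "EPSG:32637",
                     period = c("2000-01-01", "2019-12-31"),
                     cadence = c("8day", "monthly"),
                     n_grove_clusters = 5, groves_per_cluster = 6,
                     cluster_radius_m = 120,
                     grove_area_meanlog = log(0.285), grove_area_sdlog = 0.5,
                     baseline = 0.45,
                     season_amp = c(0.15, 0.12), season_doy = c(105, 315),
                     season_sd = c(30, 30),
                     background_slope_mean = 0.005, background_slope_sd = 0.015,
                     grove_effect_size = 0.15,
                     decay_length_m = 150, spill_range_m = 360,
                     effect_start = "2005-01-01",
                     noise_sd = 0.05, missing_rate = 0.15,
                     stripe_period = 16, stripe_width = 2,
                     stripe_start = "2003-06-01",
                     non_agri_fraction = 0.1, seed = 1) {
  cadence <- match.arg(cadence)
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            non_agri_fraction >= 0, non_agri_fraction <= 1,
            decay_length_m > 0, spill_range_m >= 0, noise_sd >= 0)
  sc <- list(n_rows = n_rows, n_cols = n_cols, pixel_size = pixel_size,
             crs_id = crs_id, period = as.Date(period), cadence = cadence,
             n_grove_clusters = n_grove_clusters,
             groves_per_cluster = groves_per_cluster,
             cluster_radius_m = cluster_radius_m,
             grove_area_meanlog = grove_area_meanlog,
             grove_area_sdlog = grove_area_sdlog,
             baseline = baseline, season_amp = season_amp,
             season_doy = season_doy, season_sd = season_sd,
             background_slope_mean = background_slope_mean,
             background_slope_sd = background_slope_sd,
             grove_effect_size = grove_effect_size,
             decay_length_m = decay_length_m, spill_range_m = spill_range_m,
             effect_start = as.Date(effect_start),
             noise_sd = noise_sd, missing_rate = missing_rate,
             stripe_period = stripe_period, stripe_width = stripe_width,
             stripe_start = as.Date(stripe_start),
             non_agri_fraction = non_agri_fraction,
             seed = as.integer(seed))
  class(sc) <- "scenario"
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %dx%d @ %g m, %s .. %s (%s), %d clusters x %d groves, seed %d\n",
              x$n_rows, x$n_cols, x$pixel_size, x$period[1], x$period[2],
              x$cadence, x$n_grove_clusters, x$groves_per_cluster, x$seed))
  invisible(x)
}

scene_grid <- function(sc) {
  grid_spec(sc$n_rows, sc$n_cols, origin_x = 0,
            origin_y = sc$n_rows * sc$pixel_size,
            pixel_size = sc$pixel_size, crs_id = sc$crs_id)
}

#' Generate clustered grove polygons
#'
#' Cluster centres are uniform over the scene; grove centroids scatter
#' uniformly within `cluster_radius_m` of their centre; each grove is a
#' randomly oriented rectangle with a log-normal area and mild random
#' aspect ratio. Deterministic for a fixed scenario seed.
#'
#' @param sc a [scenario].
#' @return a [grove_set].
#' @export
generate_groves <- function(sc) {
  set.seed(sc$seed)
  grid <- scene_grid(sc)
  W <- sc$n_cols * sc$pixel_size; H <- sc$n_rows * sc$pixel_size
  margin <- sc$cluster_radius_m + 100
  polys <- list(); ids <- character(0)
  if (sc$n_grove_clusters >= 1 && sc$groves_per_cluster >= 1) {
    for (cl in seq_len(sc$n_grove_clusters)) {
      cx <- stats::runif(1, margin, W - margin)
      cy <- stats::runif(1, margin, H - margin)
      for (g in seq_len(sc$groves_per_cluster)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sc$cluster_radius_m * sqrt(stats::runif(1))
        x0 <- cx + rad * cos(ang); y0 <- cy + rad * sin(ang)
        area_m2 <- 1e4 * stats::rlnorm(1, sc$grove_area_meanlog,
                                       sc$grove_area_sdlog)
        aspect <- exp(stats::runif(1, -log(1.6), log(1.6)))
        a <- sqrt(area_m2 * aspect) / 2; b <- sqrt(area_m2 / aspect) / 2
        if (2 * a > W || 2 * b > H)
          stop("generated grove exceeds the scene extent")
        th <- stats::runif(1, 0, pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
        corners <- rbind(c(-a, -b), c(a, -b), c(a, b), c(-a, b)) %*% t(R)
        ring <- sweep(corners, 2, c(x0, y0), `+`)
        polys[[length(polys) + 1]] <- list(ring)
        ids <- c(ids, sprintf("c%02d_g%02d", cl, g))
      }
    }
  }
  grove_set(polys, ids, crs_id = sc$crs_id)
}

#' Generate the study/agricultural masks
#'
#' The study area is the full scene; the agricultural mask removes a
#' square block of `non_agri_fraction` of the scene (a national-park /
#' forest stand-in), placed in the scene corner farthest from the grove
#' centroid mass. Warns if the block overlaps grove pixels (grove labels
#' take precedence downstream).
#'
#' @param sc a [scenario].
#' @param groves the [generate_groves] result.
#' @return a [study_mask].
#' @export
generate_masks <- function(sc, groves) {
  grid <- scene_grid(sc)
  study <- rep(TRUE, n_cells(grid))
  agri <- rep(TRUE, n_cells(grid))
  if (sc$non_agri_fraction > 0) {
    sr <- max(1L, round(sc$n_rows * sqrt(sc$non_agri_fraction)))
    sc_cols <- max(1L, round(sc$n_cols * sqrt(sc$non_agri_fraction)))
    if (length(groves$polygons) > 0) {
      xy <- do.call(rbind, lapply(groves$polygons,
                                  function(p) colMeans(ring_open(p[[1]]))))
      mx <- mean(xy[, 1]); my <- mean(xy[, 2])
    } else {
      mx <- 0; my <- 0
    }
    W <- sc$n_cols * sc$pixel_size; H <- sc$n_rows * sc$pixel_size
    corners <- list(tl = c(0, H), tr = c(W, H), bl = c(0, 0), br = c(W, 0))
    far <- names(which.max(vapply(corners, function(p)
      (p[1] - mx)^2 + (p[2] - my)^2, numeric(1))))
    rows <- if (far %in% c("tl", "tr")) 1:sr else (sc$n_rows - sr + 1):sc$n_rows
    cols <- if (far %in% c("tl", "bl")) 1:sc_cols else (sc$n_cols - sc_cols + 1):sc$n_cols
    block <- as.vector(outer(rows, (cols - 1L) * sc$n_rows, `+`))
    agri[block] <- FALSE
    if (length(groves$polygons) > 0) {
      gpx <- grove_pixels(groves, grid)
      if (any(gpx[block]))
        warning("non-agricultural block overlaps grove pixels; ",
                "grove labels take precedence", call. = FALSE)
    }
  }
  study_mask(grid, agricultural = agri, study_area = study)
}

acquisition_dates <- function(sc) {
  if (sc$cadence == "monthly") {
    mi <- month_index_seq(sc$period[1], sc$period[2])
    return(as.Date(sprintf("%d-%02d-15", mi$year, mi$month)))
  }
  years <- as.integer(format(sc$period[1], "%Y")):as.integer(format(sc$period[2], "%Y"))
  d <- as.Date(unlist(lapply(years, function(y)
    as.character(as.Date(paste0(y, "-01-01")) + seq(0, 360, by = 8)))))
  d[d >= sc$period[1] & d <= sc$period[2]]
}

bimodal_season <- function(sc, dates) {
  # leap-invariant day of year (Feb 29 folded onto Feb 28) so the cycle is
  # exactly periodic across years and decycling can cancel it exactly
  cum <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334)
  lt <- as.POSIXlt(dates)
  doy <- cum[lt$mon + 1L] + pmin(lt$mday, ifelse(lt$mon == 1L, 28L, 31L))
  s <- numeric(length(doy))
  for (j in seq_along(sc$season_amp)) {
    dd <- abs(doy - sc$season_doy[j])
    dd <- pmin(dd, 365 - dd)
    s <- s + sc$season_amp[j] * exp(-0.5 * (dd / sc$season_sd[j])^2)
  }
  s
}

#' Generate the synthetic NDVI stack with ground truth
#'
#' Per pixel and date: baseline + bimodal seasonal cycle + background
#' trend + grove greening ramp (exponentially decayed with distance to the
#' grove pixel set, zero beyond the spill-over range, starting at
#' `effect_start`) + Gaussian noise, clipped to `[-1, 1]`; then random
#' missingness plus periodic missing column stripes on acquisitions after
#' `stripe_start`.
#'
#' @param sc a [scenario].
#' @param groves the [generate_groves] result.
#' @return list with `stack` (an [acq_stack]) and `truth` (data frame per
#'   cell: `dist_m` -- distance to the grove pixel set, `planted_slope`
#'   and `background_slope` in NDVI/decade, and `grove` logical).
#' @export
generate_stack <- function(sc, groves) {
  set.seed(sc$seed + 1000003L)
  grid <- scene_grid(sc)
  nc <- n_cells(grid)
  dates <- acquisition_dates(sc)
  nt <- length(dates)

  gpx <- grove_pixels(groves, grid)
  d <- grove_distance(gpx, grid, max_dist = sc$spill_range_m)
  decay <- ifelse(is.finite(d), exp(-d / sc$decay_length_m), 0)
  planted <- sc$grove_effect_size * decay            # NDVI per decade
  background <- stats::rnorm(nc, sc$background_slope_mean,
                             sc$background_slope_sd)

  t_years <- as.numeric(dates - sc$period[1]) / 365.25
  ramp_years <- pmax(0, as.numeric(dates - sc$effect_start) / 365.25)
  season <- sc$baseline + bimodal_season(sc, dates)

  # one BLAS call builds deterministic structure: slopes are per decade
  vals <- tcrossprod(cbind(background / 10, planted / 10, 1),
                     cbind(t_years, ramp_years, season))
  if (sc$noise_sd > 0)
    vals <- vals + stats::rnorm(nc * nt, 0, sc$noise_sd)
  vals[vals > 1] <- 1; vals[vals < -1] <- -1

  if (sc$missing_rate > 0)
    vals[stats::runif(nc * nt) < sc$missing_rate] <- NA_real_
  if (sc$stripe_width > 0 && sc$stripe_period > 0) {
    striped <- which(dates >= sc$stripe_start)
    col_of <- ((seq_len(nc) - 1L) %/% grid$n_rows)
    phase_cells <- lapply(seq_len(sc$stripe_period) - 1L, function(ph)
      which(((col_of - ph) %% sc$stripe_period) < sc$stripe_width))
    for (k in striped)
      vals[phase_cells[[k %% sc$stripe_period + 1L]], k] <- NA_real_
  }

  truth <- data.frame(cell = seq_len(nc), dist_m = d,
                      planted_slope = planted, background_slope = background,
                      grove = gpx)
  list(stack = acq_stack(grid, dates, vals, period = sc$period,
                         validate = FALSE),
       truth = truth)
}

#' Generate a full synthetic scene
#'
#' Groves, masks and the NDVI stack in one call; optionally writes
#' everything through the package's file formats (.asc layers + manifest,
#' GeoJSON groves, .asc masks, ground-truth CSV) so file-based pipelines
#' can be exercised end to end.
#'
#' @param sc a [scenario].
#' @param dir optional output directory.
#' @return list with `groves`, `mask`, `stack`, `truth`, `grid` (and
#'   `paths` when `dir` is given).
#' @export
simulate_scene <- function(sc, dir = NULL) {
  groves <- generate_groves(sc)
  mask <- generate_masks(sc, groves)
  st <- generate_stack(sc, groves)
  out <- list(groves = groves, mask = mask, stack = st$stack,
              truth = st$truth, grid = st$stack$grid)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- write_stack(st$stack, dir)
    gpath <- file.path(dir, "groves.geojson")
    write_groves(groves, gpath)
    apath <- file.path(dir, "agricultural.asc")
    write_grid(as.numeric(mask$agricultural), mask$grid, apath)
    spath <- file.path(dir, "study_area.asc")
    write_grid(as.numeric(mask$study_area), mask$grid, spath)
    tpath <- file.path(dir, "ground_truth.csv")
    utils::write.csv(st$truth, tpath, row.names = FALSE)
    out$paths <- list(manifest = manifest, groves = gpath,
                      agricultural = apath, study_area = spath,
                      truth = tpath)
  }
  out
}
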