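# Synthetic world generator. The defaults restate the study system this
# pipeline is designed for: a flat, forested landscape with ~10% cropland and
# 3% pasture, road density 1.68 km/km2, 129 radio-collared fawns over 3
# cohort years, mean step length 415 m between radiolocations, mean telemetry
# error-ellipse area 2115 m2, and roughly half of fawns dying before 31 Aug.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. The defaults are the
#' stated study conditions; see the methods vignette for the rationale behind
#' values the study does not pin down.
#'
#' @param seed integer; fixes every generated artifact bit-for-bit.
#' @param extent numeric length-2, landscape extent in metres (x, y).
#' @param n_classes number of landcover classes (default 8).
#' @param class_targets named numeric vector of target landcover proportions
#'   for the candidate vegetation classes (length `n_classes`).
#' @param other_frac target proportion of non-candidate cover (developed,
#'   open water, ...). Keeps the candidate class proportions from summing to
#'   1 within every buffer, as in real landcover products; without it the
#'   eight proportions are perfectly collinear. `class_targets` plus
#'   `other_frac` must sum to 1.
#' @param road_density road + trail density, km per km^2.
#' @param n_fawns number of collared fawns across all years.
#' @param n_years number of cohort years.
#' @param mean_step mean step length between radiolocations (m).
#' @param step_shape gamma shape for step lengths (mean fixed at `mean_step`).
#' @param mean_ellipse_area mean telemetry error-ellipse area (m^2).
#' @param ellipse_shape gamma shape for ellipse areas; controls the fraction
#'   of locations exceeding the mean (exercised by the error filter).
#' @param lc_res landcover raster resolution (m).
#' @param ndvi_res vegetation-growth raster resolution (m).
#' @param patch_radius smoothing radius (cells) controlling landcover patch
#'   size.
#' @param true_rsf_betas named numeric vector of selection coefficients on
#'   the z-score scale used when placing telemetry (names from the landcover
#'   legend plus `dist_road`, `ndvi`).
#' @param true_cox_betas named numeric vector of log-hazard coefficients for
#'   the fate generator (z-score scale; interaction terms written `a:b`).
#' @param frailty_sd_fawn,frailty_sd_year SDs of Gaussian log-hazard
#'   frailties.
#' @param baseline_hazard daily baseline hazard h0 (constant), deaths/day.
#' @param season_length days from the start of the birth season (14 May) to
#'   the end of monitoring (31 Aug).
#' @param birth_window latest birth day (days after 14 May) in the cohort.
#' @param weather_params data.frame with one row per year and columns
#'   `snow_mean`, `snow_sd`, `wind_mean`, `wind_sd`, `rain_mean`, `rain_sd`,
#'   `tmin_mean`, `tmin_sd` (cm, kph, cm, degrees C).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    extent = c(6000, 6000),
    n_classes = 8L,
    class_targets = c(
      lowland_forest = 0.22, deciduous_forest = 0.18,
      coniferous_forest = 0.14, mixed_forest = 0.10,
      grass_shrub = 0.05, pasture = 0.03, cropland = 0.10, wetland = 0.10
    ),
    other_frac = 0.08,
    road_density = 1.68,
    n_fawns = 129L,
    n_years = 3L,
    mean_step = 415,
    step_shape = 2,
    mean_ellipse_area = 2115,
    ellipse_shape = 4,
    lc_res = 30,
    ndvi_res = 250,
    patch_radius = 6L,
    true_rsf_betas = c(
      lowland_forest = -0.157, deciduous_forest = -0.082,
      coniferous_forest = -0.130, wetland = -0.067, pasture = -0.021,
      dist_road = -0.603
    ),
    true_cox_betas = c(
      resource_use = -0.561, predation_risk = 0.165, birth_mass = -2.784,
      winter_severity = 0.146, `birth_mass:winter_severity` = -0.811
    ),
    frailty_sd_fawn = 0.3,
    frailty_sd_year = 0.3,
    baseline_hazard = 0.006,
    season_length = 109L,
    birth_window = 45L,
    weather_params = NULL) {
  if (any(extent <= 0)) stop("extent must be positive", call. = FALSE)
  if (n_classes < 1) stop("n_classes must be >= 1", call. = FALSE)
  if (frailty_sd_fawn < 0 || frailty_sd_year < 0) {
    stop("frailty SDs must be >= 0", call. = FALSE)
  }
  if (baseline_hazard < 0) {
    stop("baseline_hazard must be >= 0", call. = FALSE)
  }
  if (n_classes >= 2) {
    if (length(class_targets) != n_classes) {
      class_targets <- rep((1 - other_frac) / n_classes, n_classes)
      names(class_targets) <- paste0("class_", seq_len(n_classes))
    }
    if (abs(sum(class_targets) + other_frac - 1) > 1e-8) {
      stop("class_targets plus other_frac must sum to 1", call. = FALSE)
    }
  } else {
    class_targets <- c(class_1 = 1)
    other_frac <- 0
  }
  if (is.null(weather_params)) {
    # Mild, snow-limited winters with year-to-year contrast in severity;
    # the first year the harshest, the second the mildest.
    base <- data.frame(
      snow_mean = c(14, 4, 9), snow_sd = c(6, 3, 5),
      wind_mean = c(12, 9, 11), wind_sd = c(4, 4, 4),
      rain_mean = c(0.15, 0.25, 0.2), rain_sd = c(0.3, 0.4, 0.35),
      tmin_mean = c(-11, -4, -8), tmin_sd = c(5, 4, 5)
    )
    weather_params <- base[rep_len(seq_len(3), n_years), , drop = FALSE]
    rownames(weather_params) <- NULL
  }
  structure(list(
    seed = as.integer(seed), extent = extent, n_classes = as.integer(n_classes),
    class_targets = class_targets, other_frac = other_frac,
    road_density = road_density,
    n_fawns = as.integer(n_fawns), n_years = as.integer(n_years),
    mean_step = mean_step, step_shape = step_shape,
    mean_ellipse_area = mean_ellipse_area, ellipse_shape = ellipse_shape,
    lc_res = lc_res, ndvi_res = ndvi_res, patch_radius = as.integer(patch_radius),
    true_rsf_betas = true_rsf_betas, true_cox_betas = true_cox_betas,
    frailty_sd_fawn = frailty_sd_fawn, frailty_sd_year = frailty_sd_year,
    baseline_hazard = baseline_hazard,
    season_length = as.integer(season_length),
    birth_window = as.integer(birth_window),
    weather_params = weather_params
  ), class = "sim_config")
}

#' Generate a synthetic landscape
#'
#' Landcover is produced by smoothing independent Gaussian noise fields (one
#' per class), offsetting them, and classifying each cell by argmax; the
#' offsets are calibrated iteratively so realized class proportions match
#' `class_targets`. Predator selection surfaces and the vegetation-growth
#' raster are smoothed fields mapped to their natural ranges. Roads are
#' random chords accumulated until the target density is reached.
#'
#' @param config a [sim_config()].
#' @return list with elements `landcover` (`fs_raster` of class codes
#'   1..n_classes), `roads` (`fs_roads`), `predators` (named list of four
#'   `fs_raster`s in \[0,1\]), `ndvi` (`fs_raster`), `class_names`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$extent <= 0)) stop("extent must be positive", call. = FALSE)
  set.seed(config$seed)

  nc <- max(2L, ceiling(config$extent[1] / config$lc_res))
  nr <- max(2L, ceiling(config$extent[2] / config$lc_res))
  K <- config$n_classes
  targets <- as.numeric(config$class_targets)
  class_names <- names(config$class_targets)
  scatter_p <- 0
  if (K >= 2 && config$other_frac > 0) {
    # non-candidate cover is half patchy (lakes, towns) and half dispersed
    # single cells (roads, buildings, ponds); the scatter keeps candidate
    # class proportions off the unit simplex within buffers, as in real
    # landcover products
    scatter_p <- config$other_frac / 2
    targets <- c(targets, scatter_p) / (1 - scatter_p)
    class_names <- c(class_names, "other")
  }
  Ktot <- length(targets)

  if (Ktot == 1L) {
    lc <- fs_raster(matrix(1, nr, nc), cellsize = config$lc_res)
  } else {
    fields <- lapply(seq_len(Ktot), function(k) {
      f <- box_blur(matrix(rnorm(nr * nc), nr, nc), config$patch_radius)
      (f - mean(f)) / sd(f)
    })
    offs <- rep(0, Ktot)
    cls <- NULL
    for (it in seq_len(60L)) {
      stacked <- vapply(seq_len(Ktot), function(k) as.numeric(fields[[k]]) + offs[k],
                        numeric(nr * nc))
      cls <- max.col(stacked, ties.method = "first")
      realized <- tabulate(cls, Ktot) / (nr * nc)
      err <- targets - realized
      if (max(abs(err)) < 0.002) break
      offs <- offs + 1.5 * err
      offs <- offs - mean(offs)
    }
    if (scatter_p > 0) {
      flip <- runif(nr * nc) < scatter_p
      cls[flip] <- Ktot
    }
    lc <- fs_raster(matrix(cls, nr, nc), cellsize = config$lc_res)
  }

  predators <- lapply(PREDATOR_SPECIES, function(sp) {
    f <- box_blur(matrix(rnorm(nr * nc), nr, nc), config$patch_radius * 2L)
    f <- (f - mean(f)) / sd(f)
    fs_raster(matrix(plogis(1.2 * f), nr, nc), cellsize = config$lc_res)
  })
  names(predators) <- PREDATOR_SPECIES

  nnc <- max(2L, ceiling(config$extent[1] / config$ndvi_res))
  nnr <- max(2L, ceiling(config$extent[2] / config$ndvi_res))
  nf <- box_blur(matrix(rnorm(nnr * nnc), nnr, nnc), 3L)
  nf <- (nf - mean(nf)) / sd(nf)
  ndvi <- fs_raster(0.45 + 0.2 * nf, cellsize = config$ndvi_res)

  roads <- generate_roads(config$extent, config$road_density)

  list(landcover = lc, roads = roads, predators = predators, ndvi = ndvi,
       class_names = class_names)
}

# Random chords across the extent until total length reaches
# road_density (km/km2) * area (km2). Relies on the caller's RNG state.
generate_roads <- function(extent, road_density) {
  target_m <- road_density * prod(extent) / 1e6 * 1000
  lines <- list()
  total <- 0
  while (total < target_m) {
    # a point inside the extent and a direction; clip the full line to the box
    p <- runif(2) * extent
    th <- runif(1, 0, pi)
    d <- c(cos(th), sin(th))
    ts <- c(
      if (abs(d[1]) > 1e-12) c((0 - p[1]) / d[1], (extent[1] - p[1]) / d[1]),
      if (abs(d[2]) > 1e-12) c((0 - p[2]) / d[2], (extent[2] - p[2]) / d[2])
    )
    pts <- t(vapply(ts, function(t) p + t * d, numeric(2)))
    keep <- pts[, 1] >= -1e-9 & pts[, 1] <= extent[1] + 1e-9 &
      pts[, 2] >= -1e-9 & pts[, 2] <= extent[2] + 1e-9
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) < 2) next
    ord <- order(ts[keep])
    seg <- pts[c(ord[1], ord[length(ord)]), , drop = FALSE]
    len <- sqrt(sum((seg[2, ] - seg[1, ])^2))
    if (len < 1) next
    lines[[length(lines) + 1]] <- seg
    total <- total + len
  }
  fs_roads(lines)
}

#' Write all landscape artifacts to a directory
#'
#' Rasters go out as ESRI ASCII grids, roads as GeoJSON.
#'
#' @param landscape result of [generate_landscape()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    write_asc(landscape$landcover, file.path(dir, "landcover.asc")),
    write_asc(landscape$ndvi, file.path(dir, "ndvi.asc")),
    write_roads_geojson(landscape$roads, file.path(dir, "roads.geojson"))
  )
  for (sp in names(landscape$predators)) {
    paths <- c(paths, write_asc(landscape$predators[[sp]],
                                file.path(dir, paste0("risk_", sp, ".asc"))))
  }
  invisible(paths)
}
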