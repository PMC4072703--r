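# Telemetry, weather and fawn-metadata generators. Each generator reseeds
# from config$seed plus a fixed offset so artifacts are individually
# reproducible and jointly deterministic.

#' Generate a daily winter weather table
#'
#' One row per day from 1 Jan to 31 Mar of each cohort year, with snow depth
#' (cm), wind speed (kph), rainfall (cm) and minimum temperature (deg C)
#' drawn from the per-year parameters in the configuration. Synthetic years
#' are labelled 1..n_years with calendar dates in 2001, 2002, ...
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `year`, `date`, `snow_cm`, `wind_kph`,
#'   `rain_cm`, `tmin_c`.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  out <- lapply(seq_len(config$n_years), function(y) {
    p <- config$weather_params[y, ]
    dates <- seq(as.Date(sprintf("%d-01-01", 2000 + y)),
                 as.Date(sprintf("%d-03-31", 2000 + y)), by = "day")
    n <- length(dates)
    data.frame(
      year = y, date = dates,
      snow_cm = pmax(0, rnorm(n, p$snow_mean, p$snow_sd)),
      wind_kph = pmax(0, rnorm(n, p$wind_mean, p$wind_sd)),
      rain_cm = pmax(0, rnorm(n, p$rain_mean, p$rain_sd)),
      tmin_c = rnorm(n, p$tmin_mean, p$tmin_sd)
    )
  })
  do.call(rbind, out)
}

#' Generate fawn capture metadata
#'
#' Birth dates are indexed in days from the start of the birth season
#' (14 May = day 0) and peak near 1 June. Birth mass responds negatively to
#' the preceding winter's severity (maternal nutritional carry-over), and
#' capture mass back-projects the 0.2 kg/day neonatal gain over the age at
#' capture (0-15 days).
#'
#' @param config a [sim_config()].
#' @param weather optional weather table from [generate_weather()]; generated
#'   if missing.
#' @return data.frame with columns `fawn_id`, `year`, `birth_date`,
#'   `birth_mass_true`, `capture_mass`, `age_at_capture`, `sex`.
#' @export
generate_fawns <- function(config, weather = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(weather)) weather <- generate_weather(config)
  set.seed(config$seed + 2L)
  sev <- vapply(seq_len(config$n_years), function(y) {
    winter_severity(weather[weather$year == y, ])
  }, numeric(1))
  sev_z <- if (length(sev) > 1 && sd(sev) > 0) (sev - mean(sev)) / sd(sev) else sev * 0
  n <- config$n_fawns
  year <- sort(rep_len(seq_len(config$n_years), n))
  birth_date <- pmax(0L, pmin(config$birth_window,
                              round(rnorm(n, mean = 18, sd = 8))))
  age_at_capture <- pmin(15L, stats::rpois(n, 4))
  birth_mass_true <- pmax(1.2, 4.0 - 0.8 * sev_z[year] + rnorm(n, 0, 0.85))
  data.frame(
    fawn_id = sprintf("F%03d", seq_len(n)),
    year = year,
    birth_date = as.integer(birth_date),
    birth_mass_true = birth_mass_true,
    capture_mass = birth_mass_true + 0.2 * age_at_capture,
    age_at_capture = as.integer(age_at_capture),
    sex = sample(c("M", "F"), n, replace = TRUE)
  )
}

#' Generate fawn radio-telemetry
#'
#' Per fawn, 2-56 locations: a uniform start point, then gamma step lengths
#' (mean `mean_step`) in headings chosen by weighted habitat selection -- at
#' each step several candidate destinations are proposed and one is kept with
#' probability proportional to `exp(beta . z)` using the configuration's true
#' selection coefficients on point-level covariates. Each location carries a
#' gamma-distributed error-ellipse area with mean `mean_ellipse_area`.
#'
#' @param config a [sim_config()].
#' @param landscape result of [generate_landscape()].
#' @param fawns optional metadata from [generate_fawns()].
#' @return data.frame with columns `fawn_id`, `year`, `day` (days since
#'   14 May), `x`, `y`, `ellipse_area`.
#' @export
generate_telemetry <- function(config, landscape, fawns = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(fawns)) fawns <- generate_fawns(config)
  if (nrow(fawns) == 0) {
    warning("n_fawns = 0: returning an empty telemetry table")
    return(data.frame(fawn_id = character(), year = integer(),
                      day = integer(), x = numeric(), y = numeric(),
                      ellipse_area = numeric()))
  }
  set.seed(config$seed + 3L)
  ext <- config$extent
  inset <- min(500, min(ext) / 4)

  # z-scaling reference for point covariates, from a background sample
  bg <- cbind(runif(2000, 0, ext[1]), runif(2000, 0, ext[2]))
  bgX <- point_covariates(bg[, 1], bg[, 2], landscape)
  mu <- colMeans(bgX); sg <- apply(bgX, 2, sd); sg[sg == 0] <- 1
  betas <- config$true_rsf_betas
  bnames <- intersect(names(betas), colnames(bgX))

  n_candidates <- 8L
  rows <- vector("list", nrow(fawns))
  for (i in seq_len(nrow(fawns))) {
    n_loc <- sample(2:56, 1)
    xy <- matrix(NA_real_, n_loc, 2)
    xy[1, ] <- c(runif(1, inset, ext[1] - inset), runif(1, inset, ext[2] - inset))
    for (j in 2:n_loc) {
      # propose candidate destinations until enough fall inside the extent
      cand <- matrix(NA_real_, 0, 2)
      tries <- 0L
      while (nrow(cand) < n_candidates && tries < 20L) {
        steps <- rgamma(n_candidates, shape = config$step_shape,
                        scale = config$mean_step / config$step_shape)
        th <- runif(n_candidates, 0, 2 * pi)
        prop <- cbind(xy[j - 1, 1] + steps * cos(th),
                      xy[j - 1, 2] + steps * sin(th))
        ok <- prop[, 1] >= 0 & prop[, 1] <= ext[1] &
          prop[, 2] >= 0 & prop[, 2] <= ext[2]
        cand <- rbind(cand, prop[ok, , drop = FALSE])
        tries <- tries + 1L
      }
      if (nrow(cand) == 0) cand <- xy[j - 1, , drop = FALSE]
      cx <- point_covariates(cand[, 1], cand[, 2], landscape)
      z <- sweep(sweep(cx[, bnames, drop = FALSE], 2, mu[bnames]), 2,
                 sg[bnames], "/")
      w <- exp(drop(z %*% betas[bnames]))
      pick <- sample.int(nrow(cand), 1, prob = w)
      xy[j, ] <- cand[pick, ]
    }
    gaps <- pmax(1, round(rexp(n_loc - 1, 1 / 1.6)))
    day <- fawns$birth_date[i] + cumsum(c(sample(0:3, 1), gaps))
    rows[[i]] <- data.frame(
      fawn_id = fawns$fawn_id[i], year = fawns$year[i],
      day = as.integer(pmin(day, config$season_length)),
      x = xy[, 1], y = xy[, 2],
      ellipse_area = rgamma(n_loc, shape = config$ellipse_shape,
                            scale = config$mean_ellipse_area / config$ellipse_shape)
    )
  }
  do.call(rbind, rows)
}

# Point-level covariates used by the movement kernel: landcover class
# indicators, distance to road, and vegetation growth at the point.
point_covariates <- function(x, y, landscape) {
  cls <- raster_lookup(landscape$landcover, x, y)
  K <- max(landscape$landcover$values, na.rm = TRUE)
  ind <- matrix(0, length(x), K)
  for (k in seq_len(K)) ind[, k] <- as.numeric(cls == k)
  cn <- landscape$class_names
  if (length(cn) != K) cn <- paste0("class_", seq_len(K))
  colnames(ind) <- cn
  cbind(ind,
        dist_road = dist_to_road(x, y, landscape$roads),
        ndvi = raster_lookup(landscape$ndvi, x, y))
}
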