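# Survival covariates: composite multi-predator risk, the winter severity
# index, back-calculated birth mass, and the per-fawn covariate table that
# feeds the proportional-hazards model set.

#' Composite multi-predator predation risk
#'
#' The sum across the four predator species (bobcat, black bear, coyote,
#' wolf) of each species' mean selection probability, per buffer sample or
#' per grid cell. With each species surface in \[0, 1\] the composite is
#' bounded in \[0, 4\].
#'
#' @param x data.frame with one `risk_<species>` column per predator (a
#'   buffer-sample table or a `landscape_grid`).
#' @return numeric vector of composite risk values.
#' @export
composite_risk <- function(x) {
  cols <- paste0("risk_", PREDATOR_SPECIES)
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop("missing predator risk layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unname(rowSums(as.data.frame(x)[cols]))
}

#' Winter severity index
#'
#' Daily severity `d = (snow + wind + rain) - tmin`, summed over the window
#' (default 1 Jan - 31 Mar); increasing values indicate greater severity
#' (deep snow, wind, rain, cold minima). The literal sign convention
#' `d = tmin - (snow + wind + rain)` is available behind a flag but
#' decreases with severity; see the methods vignette.
#'
#' @param weather data.frame with columns `date`, `snow_cm`, `wind_kph`,
#'   `rain_cm`, `tmin_c` (one row per day).
#' @param start,end window bounds (Date or coercible); default the full
#'   Jan-Mar span of the supplied series.
#' @param convention `"severity"` (default, `sum - tmin`) or `"literal"`
#'   (`tmin - sum`).
#' @param allow_gaps if FALSE (default), missing days inside the window are
#'   an error listing the dates.
#' @return numeric scalar index.
#' @export
winter_severity <- function(weather, start = NULL, end = NULL,
                            convention = c("severity", "literal"),
                            allow_gaps = FALSE) {
  convention <- match.arg(convention)
  need <- c("date", "snow_cm", "wind_kph", "rain_cm", "tmin_c")
  missing_cols <- setdiff(need, names(weather))
  if (length(missing_cols)) {
    stop("weather table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(weather$snow_cm < 0 | weather$wind_kph < 0 | weather$rain_cm < 0,
          na.rm = TRUE)) {
    stop("snow, wind and rain must be >= 0", call. = FALSE)
  }
  d <- as.Date(weather$date)
  if (is.null(start)) start <- min(d)
  if (is.null(end)) end <- max(d)
  start <- as.Date(start); end <- as.Date(end)
  win <- weather[d >= start & d <= end, , drop = FALSE]
  expected <- seq(start, end, by = "day")
  gaps <- setdiff(as.character(expected), as.character(as.Date(win$date)))
  if (length(gaps) && !allow_gaps) {
    stop("missing weather day(s): ", paste(head(gaps, 10), collapse = ", "),
         if (length(gaps) > 10) sprintf(" (+%d more)", length(gaps) - 10),
         call. = FALSE)
  }
  daily <- (win$snow_cm + win$wind_kph + win$rain_cm) - win$tmin_c
  if (convention == "literal") daily <- -daily
  sum(daily)
}

#' Back-calculate birth mass from capture mass
#'
#' Subtracts the average neonatal daily mass gain (0.2 kg/day) over the age
#' at capture. The default interprets the gain per day of age
#' (`mass - gain * age`); `mode = "literal"` performs the single subtraction
#' (`mass - gain`) regardless of age. Non-positive results are floored at
#' 0.1 kg with a warning.
#'
#' @param capture_mass capture mass (kg), > 0.
#' @param age_at_capture age at capture in days (0-15).
#' @param daily_gain daily mass gain (kg/day), default 0.2.
#' @param mode `"per_day"` (default) or `"literal"`.
#' @return estimated birth mass (kg).
#' @export
birth_mass <- function(capture_mass, age_at_capture, daily_gain = 0.2,
                       mode = c("per_day", "literal")) {
  mode <- match.arg(mode)
  if (any(capture_mass <= 0)) stop("capture_mass must be > 0", call. = FALSE)
  if (any(age_at_capture < 0 | age_at_capture > 15)) {
    stop("age_at_capture must be in [0, 15] days", call. = FALSE)
  }
  out <- if (mode == "per_day") {
    capture_mass - daily_gain * age_at_capture
  } else {
    capture_mass - daily_gain
  }
  bad <- out <= 0
  if (any(bad)) {
    warning(sum(bad), " birth mass estimate(s) <= 0 floored at 0.1 kg")
    out[bad] <- 0.1
  }
  out
}

#' Build the per-fawn survival covariate table
#'
#' For each fawn, averages buffer-level resource suitability, composite
#' predation risk and vegetation growth over that fawn's retained
#' radiolocations, attaches the year-level winter severity index and
#' back-calculated birth mass, and z-scores all model covariates over fawns
#' (retaining the scaler for spatial extrapolation).
#'
#' @param telemetry error-filtered telemetry table.
#' @param suitability a `risk_surface` of kind `"suitability"`.
#' @param grid the `landscape_grid` (source of per-cell composite risk).
#' @param landscape landscape list (vegetation-growth raster and buffers).
#' @param weather weather table (see [generate_weather()]).
#' @param metadata fawn metadata (`fawn_id`, `year`, `capture_mass`,
#'   `age_at_capture`).
#' @param radius buffer radius (m).
#' @param severity_convention passed to [winter_severity()].
#' @param birth_mass_mode passed to [birth_mass()].
#' @return list with `table` (one row per fawn: ids, raw and z-scored
#'   covariates `resource_use`, `predation_risk`, `birth_mass`,
#'   `winter_severity`, `veg_growth`) and `scaler`.
#' @export
fawn_covariates <- function(telemetry, suitability, grid, landscape, weather,
                            metadata, radius = 26,
                            severity_convention = "severity",
                            birth_mass_mode = "per_day") {
  suit_r <- surface_to_raster(suitability)
  comp <- composite_risk(grid)
  comp_r <- grid_to_raster(transform_grid(grid, composite = comp), "composite")

  suit_vals <- buffer_means(telemetry, suit_r, radius)
  comp_vals <- buffer_means(telemetry, comp_r, radius)
  ndvi_vals <- buffer_means(telemetry, landscape$ndvi, radius)

  agg <- data.frame(fawn_id = telemetry$fawn_id, year = telemetry$year,
                    suit = suit_vals, comp = comp_vals, ndvi = ndvi_vals)
  per_fawn <- aggregate(cbind(suit, comp, ndvi) ~ fawn_id + year, data = agg,
                        FUN = mean, na.action = stats::na.omit)

  missing_fawns <- setdiff(metadata$fawn_id, per_fawn$fawn_id)
  if (length(missing_fawns)) {
    warning("excluding ", length(missing_fawns),
            " fawn(s) with zero retained locations: ",
            paste(head(missing_fawns, 5), collapse = ", "))
  }
  meta <- metadata[metadata$fawn_id %in% per_fawn$fawn_id, , drop = FALSE]
  tab <- merge(meta, per_fawn, by = c("fawn_id", "year"), sort = TRUE)

  years <- sort(unique(tab$year))
  sev <- vapply(years, function(y) {
    winter_severity(weather[weather$year == y, , drop = FALSE],
                    convention = severity_convention)
  }, numeric(1))

  tab$resource_use <- tab$suit
  tab$predation_risk <- tab$comp
  tab$veg_growth <- tab$ndvi
  tab$birth_mass <- birth_mass(tab$capture_mass, tab$age_at_capture,
                               mode = birth_mass_mode)
  tab$winter_severity <- sev[match(tab$year, years)]
  tab <- tab[order(tab$fawn_id), , drop = FALSE]
  rownames(tab) <- NULL

  covs <- c("resource_use", "predation_risk", "birth_mass",
            "winter_severity", "veg_growth")
  std <- standardize(tab, covs)
  list(table = std$table, scaler = std$scaler, raw = tab)
}

# area-weighted mean raster value inside the buffer disc around each
# telemetry point
buffer_means <- function(telemetry, r, radius) {
  disc_mean(r, telemetry$x, telemetry$y, radius)
}

# append a column to a landscape_grid without losing its attributes
transform_grid <- function(grid, ...) {
  extra <- list(...)
  at <- attributes(grid)
  for (nm in names(extra)) grid[[nm]] <- extra[[nm]]
  for (a in c("n_rows", "n_cols", "cellsize", "origin", "class_names")) {
    attr(grid, a) <- at[[a]]
  }
  class(grid) <- c("landscape_grid", "data.frame")
  grid
}
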