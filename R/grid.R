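# Landscape grid and zonal extraction. The analysis grid is a tessellation
# of non-overlapping square cells whose area equals the mean telemetry
# error-ellipse (2115 m2, side ~45.99 m). Buffer extraction around points
# uses a 26 m radius disc (the mean-ellipse radius) and supersampled zonal
# statistics.

#' Linear stretch to \[0, 1\]
#'
#' `(v - min) / (max - min)`; the minimum maps to 0 and the maximum to 1,
#' preserving rank order. A constant input has no range to stretch; it maps
#' to all zeros with a warning.
#'
#' @param values numeric vector with at least one finite value.
#' @return numeric vector in \[0, 1\].
#' @export
linear_stretch <- function(values) {
  fin <- is.finite(values)
  if (!any(fin)) stop("linear_stretch needs at least one finite value", call. = FALSE)
  lo <- min(values[fin]); hi <- max(values[fin])
  if (hi == lo) {
    warning("degenerate stretch: all values equal; returning zeros")
    out <- values
    out[fin] <- 0
    return(out)
  }
  (values - lo) / (hi - lo)
}

#' Discard telemetry locations with large error ellipses
#'
#' Removes rows whose error-ellipse area exceeds the threshold (strictly
#' larger; areas equal to the threshold are retained) and reports the count
#' removed.
#'
#' @param telemetry data.frame with an `ellipse_area` column.
#' @param threshold area threshold in m^2 (default the 2115 m^2 mean).
#' @return the filtered telemetry table.
#' @export
filter_by_error <- function(telemetry, threshold = 2115) {
  if (!"ellipse_area" %in% names(telemetry)) {
    stop("telemetry table has no 'ellipse_area' column", call. = FALSE)
  }
  keep <- telemetry$ellipse_area <= threshold
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("filter_by_error: discarded %d of %d locations (ellipse area > %g m^2)",
                    dropped, nrow(telemetry), threshold))
  }
  telemetry[keep, , drop = FALSE]
}

#' Pair each used location with a random available point
#'
#' One available point per used point, uniform over the disc of radius
#' `radius` (the cumulative mean step length, 415 m) centred on the used
#' point; points falling outside the study extent are resampled.
#'
#' @param used data.frame or matrix with `x`, `y` columns.
#' @param radius availability radius in metres.
#' @param extent numeric length-2 (xmax, ymax) of the study extent, with
#'   origin at (0, 0).
#' @param seed RNG seed.
#' @return data.frame with columns `x`, `y`, one row per used point, in
#'   order.
#' @export
sample_availability <- function(used, radius = 415, extent, seed = 1) {
  stopifnot(radius > 0, length(extent) == 2)
  ux <- used[, "x"]; uy <- used[, "y"]
  n <- length(ux)
  # a used point whose whole disc lies outside the extent can never yield a
  # sample; detect via the clamped nearest in-extent point
  nx <- pmin(pmax(ux, 0), extent[1]); ny <- pmin(pmax(uy, 0), extent[2])
  if (any((nx - ux)^2 + (ny - uy)^2 > radius^2)) {
    stop("used point(s) with no in-extent disc area", call. = FALSE)
  }
  set.seed(seed)
  ax <- rep(NA_real_, n); ay <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    r <- radius * sqrt(runif(m))
    th <- runif(m, 0, 2 * pi)
    px <- ux[todo] + r * cos(th)
    py <- uy[todo] + r * sin(th)
    ok <- px >= 0 & px <= extent[1] & py >= 0 & py <= extent[2]
    ax[todo[ok]] <- px[ok]; ay[todo[ok]] <- py[ok]
    todo <- todo[!ok]
  }
  data.frame(x = ax, y = ay)
}

#' Zonal statistics within circular buffers
#'
#' Area-weighted landcover class proportions and mean surface values within
#' a disc around each point. Because raster class regions are unions of
#' axis-aligned square cells, the statistics use exact circle-rectangle
#' intersection areas (chord-length quadrature), free of supersampling
#' artefacts.
#'
#' @param centers data.frame or matrix with `x`, `y` columns (one row per
#'   buffer), or a length-2 numeric vector for a single buffer.
#' @param radius buffer radius in metres (default 26, the mean-ellipse
#'   radius).
#' @param landscape a landscape list as returned by [generate_landscape()]
#'   (elements `landcover`, `roads`, `predators`, `ndvi`, `class_names`).
#' @return data.frame, one row per buffer: `x`, `y`, one proportion column
#'   per landcover class, `ndvi`, one `risk_*` column per predator, and
#'   `dist_road` (distance from the buffer centre).
#' @export
extract_buffer <- function(centers, radius = 26, landscape) {
  stopifnot(radius > 0)
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2,
                                               dimnames = list(NULL, c("x", "y")))
  cx <- centers[, "x"]; cy <- centers[, "y"]
  ext <- raster_extent(landscape$landcover)
  out_of <- cx + radius < ext["xmin"] | cx - radius > ext["xmax"] |
    cy + radius < ext["ymin"] | cy - radius > ext["ymax"]
  if (any(out_of)) stop("buffer(s) wholly outside the raster extent", call. = FALSE)

  K <- length(landscape$class_names)
  props <- disc_class_proportions(landscape$landcover, cx, cy, radius, K)
  colnames(props) <- landscape$class_names

  res <- data.frame(x = cx, y = cy, check.names = FALSE)
  res <- cbind(res, as.data.frame(props))
  res$ndvi <- disc_mean(landscape$ndvi, cx, cy, radius)
  for (sp in names(landscape$predators)) {
    res[[paste0("risk_", sp)]] <- disc_mean(landscape$predators[[sp]],
                                            cx, cy, radius)
  }
  res$dist_road <- dist_to_road(cx, cy, landscape$roads)
  res
}

#' Build the analysis grid
#'
#' Tessellates the landscape into non-overlapping square cells of
#' `cell_area` m^2 (side `sqrt(cell_area)`), indexed row-major from the
#' top-left, and populates each cell with exact area-weighted landcover
#' class proportions, mean vegetation growth, mean per-species predation
#' risk, and centroid distance to the nearest road.
#'
#' @param landscape landscape list (see [extract_buffer()]).
#' @param cell_area cell area in m^2 (default 2115, the mean error ellipse).
#' @return object of class `landscape_grid`: a data.frame with one row per
#'   cell (`cell`, `row`, `col`, `x`, `y`, class proportions, `ndvi`,
#'   `risk_*`, `dist_road`) and attributes `n_rows`, `n_cols`, `cellsize`,
#'   `origin`, `class_names`.
#' @export
build_grid <- function(landscape, cell_area = 2115) {
  stopifnot(cell_area > 0)
  side <- sqrt(cell_area)
  ext <- raster_extent(landscape$landcover)
  for (nm in names(landscape$predators)) {
    e2 <- raster_extent(landscape$predators[[nm]])
    if (any(abs(e2 - ext) > 1e-6)) {
      stop("raster extent mismatch: predator layer '", nm, "'", call. = FALSE)
    }
  }
  e3 <- raster_extent(landscape$ndvi)
  if (e3["xmax"] < ext["xmax"] - landscape$ndvi$cellsize ||
      e3["ymax"] < ext["ymax"] - landscape$ndvi$cellsize) {
    stop("raster extent mismatch: ndvi layer", call. = FALSE)
  }

  n_cols <- max(1L, floor((ext["xmax"] - ext["xmin"]) / side + 1e-9))
  n_rows <- max(1L, floor((ext["ymax"] - ext["ymin"]) / side + 1e-9))
  col <- rep(seq_len(n_cols), times = n_rows)
  row <- rep(seq_len(n_rows), each = n_cols)
  # centroids; row 1 at the top
  x <- ext["xmin"] + (col - 0.5) * side
  y <- ext["ymax"] - (row - 0.5) * side
  n <- n_rows * n_cols
  x <- as.numeric(x); y <- as.numeric(y)

  K <- length(landscape$class_names)
  props <- square_class_proportions(landscape$landcover, x, y, side, K)
  colnames(props) <- landscape$class_names

  grid <- data.frame(cell = seq_len(n), row = row, col = col, x = x, y = y)
  grid <- cbind(grid, as.data.frame(props))
  grid$ndvi <- square_mean(landscape$ndvi, x, y, side)
  for (sp in names(landscape$predators)) {
    grid[[paste0("risk_", sp)]] <- square_mean(landscape$predators[[sp]],
                                               x, y, side)
  }
  grid$dist_road <- dist_to_road(grid$x, grid$y, landscape$roads)

  structure(grid,
            n_rows = n_rows, n_cols = n_cols, cellsize = side,
            origin = c(ext["xmin"], ext["ymin"]),
            class_names = landscape$class_names,
            class = c("landscape_grid", "data.frame"))
}

#' Turn one grid column into a raster
#' @param grid a `landscape_grid`.
#' @param column column name to rasterize.
#' @return an `fs_raster` (row-major from top-left, same georeference as the
#'   grid).
#' @export
grid_to_raster <- function(grid, column) {
  stopifnot(inherits(grid, "landscape_grid"), column %in% names(grid))
  nr <- attr(grid, "n_rows"); ncg <- attr(grid, "n_cols")
  m <- matrix(grid[[column]], nrow = nr, ncol = ncg, byrow = TRUE)
  org <- attr(grid, "origin")
  fs_raster(m, xmin = org[1], ymin = org[2], cellsize = attr(grid, "cellsize"))
}
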