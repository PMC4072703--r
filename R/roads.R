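# Road / trail line layer: a list of polylines, each an n x 2 coordinate
# matrix in planar metres. Distances are exact point-to-segment minima; at
# the scale of a study area (tens of km of road) exhaustive minimization is
# both fast and serves as its own closed form.

#' Create a road line layer
#' @param lines list of numeric matrices, each n x 2 (x, y) with n >= 2.
#' @return an object of class `fs_roads`.
#' @export
fs_roads <- function(lines) {
  stopifnot(is.list(lines), length(lines) > 0)
  for (l in lines) stopifnot(is.matrix(l), ncol(l) == 2, nrow(l) >= 2)
  structure(list(lines = lines), class = "fs_roads")
}

#' @export
print.fs_roads <- function(x, ...) {
  cat(sprintf("<fs_roads> %d polylines, total length %.1f km\n",
              length(x$lines), roads_length(x) / 1000))
  invisible(x)
}

#' Total length of a road layer (m)
#' @param roads an `fs_roads`.
#' @export
roads_length <- function(roads) {
  sum(vapply(roads$lines, function(l) {
    sum(sqrt(rowSums(diff(l)^2)))
  }, numeric(1)))
}

# Flatten polylines to a segment table (x1, y1, x2, y2).
road_segments <- function(roads) {
  segs <- lapply(roads$lines, function(l) {
    cbind(l[-nrow(l), 1], l[-nrow(l), 2], l[-1, 1], l[-1, 2])
  })
  do.call(rbind, segs)
}

#' Distance from points to the nearest road
#'
#' Exhaustive minimum over all road segments of the perpendicular (or
#' endpoint) distance, vectorized over points.
#'
#' @param x,y point coordinates (m).
#' @param roads an `fs_roads`.
#' @return numeric vector of distances (m), `>= 0`.
#' @export
dist_to_road <- function(x, y, roads) {
  stopifnot(inherits(roads, "fs_roads"))
  segs <- road_segments(roads)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  out <- rep(Inf, n)
  # chunk over points to bound the n x m working set
  chunk <- max(1L, floor(2e6 / nrow(segs)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx] <- point_segment_min(x[idx], y[idx], segs)
  }
  out
}

point_segment_min <- function(px, py, segs) {
  dx <- segs[, 3] - segs[, 1]
  dy <- segs[, 4] - segs[, 2]
  len2 <- dx^2 + dy^2
  # t parameter of the projection for each point x segment pair
  tx <- outer(px, segs[, 1], "-") # n x m
  ty <- outer(py, segs[, 2], "-")
  tt <- sweep(sweep(tx, 2, dx, "*") + sweep(ty, 2, dy, "*"), 2, len2, "/")
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  ex <- tx - sweep(tt, 2, dx, "*")
  ey <- ty - sweep(tt, 2, dy, "*")
  sqrt(apply(ex^2 + ey^2, 1, min))
}

#' Write roads as GeoJSON LineStrings
#' @param roads an `fs_roads`.
#' @param path output file path.
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- lapply(roads$lines, function(l) {
    list(
      type = "Feature",
      properties = list(kind = "road"),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(l)), function(i) unname(l[i, ]))
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read roads from GeoJSON LineStrings
#' @param path file path.
#' @return an `fs_roads`.
#' @export
read_roads_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lines <- lapply(gj$features, function(f) {
    stopifnot(identical(f$geometry$type, "LineString"))
    do.call(rbind, lapply(f$geometry$coordinates, function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
  })
  fs_roads(lines)
}
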