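# Minimal single-band planar raster: a numeric matrix stored row-major from
# the top-left (row 1 = northernmost), with a lower-left anchor and square
# cells. All coordinates are planar metres.

#' Create a single-band planar raster
#'
#' @param values numeric matrix; row 1 is the top (largest y) row.
#' @param xmin,ymin coordinates of the lower-left corner of the grid (m).
#' @param cellsize cell side length (m).
#' @return an object of class `fs_raster`.
#' @export
fs_raster <- function(values, xmin = 0, ymin = 0, cellsize = 30) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "fs_raster"
  )
}

#' @export
print.fs_raster <- function(x, ...) {
  cat(sprintf(
    "<fs_raster> %d x %d cells, %.6g m resolution, extent x [%.6g, %.6g] y [%.6g, %.6g]\n",
    nrow(x$values), ncol(x$values), x$cellsize,
    x$xmin, raster_xmax(x), x$ymin, raster_ymax(x)
  ))
  invisible(x)
}

raster_xmax <- function(r) r$xmin + ncol(r$values) * r$cellsize
raster_ymax <- function(r) r$ymin + nrow(r$values) * r$cellsize

#' Extent of a raster as (xmin, xmax, ymin, ymax)
#' @param r an `fs_raster`.
#' @export
raster_extent <- function(r) {
  c(xmin = r$xmin, xmax = raster_xmax(r), ymin = r$ymin, ymax = raster_ymax(r))
}

#' Look up raster values at point coordinates
#'
#' Nearest-cell lookup; points outside the extent return `NA`.
#'
#' @param r an `fs_raster`.
#' @param x,y point coordinates (m), recycled to common length.
#' @return numeric vector of cell values.
#' @export
raster_lookup <- function(r, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  row <- nrow(r$values) - floor((y - r$ymin) / r$cellsize)
  ok <- col >= 1L & col <= ncol(r$values) & row >= 1L & row <= nrow(r$values)
  out <- rep(NA_real_, n)
  if (any(ok)) out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format: a six-line header followed by rows of cell
#' values from the top row down.
#'
#' @param r an `fs_raster`.
#' @param path output file path.
#' @param digits significant digits for cell values.
#' @export
write_asc <- function(r, path, digits = 8) {
  stopifnot(inherits(r, "fs_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$cellsize),
    "NODATA_value -9999"
  ), con)
  v <- r$values
  v[is.na(v)] <- -9999
  body <- apply(signif(v, digits), 1, paste, collapse = " ")
  writeLines(body, con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @return an `fs_raster`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- lapply(strsplit(trimws(body), "[[:space:]]+"), as.numeric)
  m <- do.call(rbind, vals)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  stopifnot(nrow(m) == hdr$nrows, ncol(m) == hdr$ncols)
  fs_raster(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
            cellsize = hdr$cellsize)
}

# Shared smoothing primitive for the landscape generator: iterated box blur
# of a matrix using cumulative sums (edge-renormalized), giving an
# approximately Gaussian kernel after a few passes.
box_blur <- function(m, radius, passes = 3L) {
  if (radius < 1) return(m)
  ones <- matrix(1, nrow(m), ncol(m))
  for (p in seq_len(passes)) {
    m <- box_sum(m, radius) / box_sum(ones, radius)
  }
  m
}

box_sum <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  # rows
  cs <- apply(m, 2, cumsum)
  up <- pmin(seq_len(nr) + radius, nr)
  lo <- seq_len(nr) - radius - 1L
  out <- cs[up, , drop = FALSE] -
    rbind(matrix(0, sum(lo < 1), nc), cs[lo[lo >= 1], , drop = FALSE])
  # cols
  cs <- t(apply(out, 1, cumsum))
  up <- pmin(seq_len(nc) + radius, nc)
  lo <- seq_len(nc) - radius - 1L
  out <- cs[, up, drop = FALSE] -
    cbind(matrix(0, nr, sum(lo < 1)), cs[, lo[lo >= 1], drop = FALSE])
  out
}
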