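# Spatial extrapolation of a fitted survival model: per-cell end-of-season
# survival S(te | x) = S0_j(te)^exp(beta . x), averaged over year-specific
# Breslow baselines, mapped to a stretched mortality surface (values near 1
# = greater likelihood of fawn mortality).

#' Spatially extrapolated mortality surface
#'
#' For every grid cell, z-scores the spatial covariates of the fitted model
#' through the survival scaler, computes the fixed-effect linear predictor,
#' powers each year's baseline cumulative survival at the horizon
#' `S0_j(te)^exp(lp)`, averages survival over years with equal weights, and
#' returns `linear_stretch(1 - S)`.
#'
#' @param fit a `cox_fit` whose terms are all available on the grid (e.g.
#'   the non-ideal resource-use model: `resource_use` + `predation_risk`).
#' @param grid a `landscape_grid` carrying per-cell columns for every main
#'   effect of `fit` (raw scale).
#' @param scaler the survival-covariate scaler from [fawn_covariates()].
#' @param te horizon in days since birth (default: the latest horizon every
#'   year's baseline covers); must not exceed the observed follow-up in any
#'   year used.
#' @param years optional subset of years to average over.
#' @return a `risk_surface` of kind `"mortality"`.
#' @export
mortality_surface <- function(fit, grid, scaler, te = NULL, years = NULL) {
  mains <- unique(unlist(strsplit(fit$terms, ":", fixed = TRUE)))
  missing <- setdiff(mains, names(grid))
  if (length(missing)) {
    stop("grid lacks covariate column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  base <- fit$baseline
  if (is.null(years)) years <- sort(unique(base$year))
  max_t <- min(vapply(years, function(y) max(base$time[base$year == y]),
                      numeric(1)))
  # default horizon: the latest day-since-birth covered by every year's
  # baseline (follow-up to the season end differs across birth dates)
  if (is.null(te)) te <- max_t
  if (te > max_t + 1e-9) {
    stop(sprintf(
      "horizon te = %g exceeds observed follow-up (%g days); refusing to extrapolate",
      te, max_t), call. = FALSE)
  }
  z <- apply_scaler(as.data.frame(grid)[mains], scaler)
  X <- build_term_matrix(z, fit$terms)
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)[fit$terms]
  lp <- drop(X %*% beta)

  S <- rowMeans(vapply(years, function(y) {
    b <- base[base$year == y, ]
    S0 <- b$S0[findInterval(te, b$time)]
    S0^exp(lp)
  }, numeric(nrow(grid))))
  new_risk_surface(grid, linear_stretch(1 - S), kind = "mortality",
                   provenance = sprintf("%s @ te=%g", fit$model_name, te))
}

#' Composite predation-risk surface on the grid
#'
#' Per-cell sum of the four species' risk values, stretched to \[0, 1\].
#'
#' @param grid a `landscape_grid`.
#' @return a `risk_surface` of kind `"composite_risk"`.
#' @export
composite_risk_surface <- function(grid) {
  new_risk_surface(grid, linear_stretch(composite_risk(grid)),
                   kind = "composite_risk", provenance = "sum of 4 species")
}

#' Bundle the three display surfaces
#'
#' Checks that the suitability, composite-risk and mortality surfaces share
#' one grid, writes each as an ESRI ASCII grid, and emits a combined
#' per-cell CSV (row, col, x, y, suitability, composite_risk, mortality).
#'
#' @param suitability,composite,mortality aligned `risk_surface`s.
#' @param grid the shared `landscape_grid`.
#' @param dir output directory, or NULL to skip writing.
#' @return (invisibly) the combined per-cell data.frame.
#' @export
surface_panel <- function(suitability, composite, mortality, grid, dir = NULL) {
  surfs <- list(suitability = suitability, composite_risk = composite,
                mortality = mortality)
  for (nm in names(surfs)) {
    s <- surfs[[nm]]
    if (s$n_rows != attr(grid, "n_rows") || s$n_cols != attr(grid, "n_cols") ||
        abs(s$cellsize - attr(grid, "cellsize")) > 1e-9 ||
        any(abs(s$origin - attr(grid, "origin")) > 1e-6)) {
      stop("surface '", nm, "' is not aligned with the grid", call. = FALSE)
    }
  }
  out <- data.frame(
    row = grid$row, col = grid$col, x = grid$x, y = grid$y,
    suitability = suitability$values,
    composite_risk = composite$values,
    mortality = mortality$values
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(surfs)) {
      write_asc(surface_to_raster(surfs[[nm]]),
                file.path(dir, paste0("surface_", nm, ".asc")))
    }
    write.csv(out, file.path(dir, "surface_panel.csv"), row.names = FALSE)
  }
  invisible(out)
}
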