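# Use-availability resource selection: third-order design with used
# radiolocations (1) contrasted against paired random points (0), mixed
# logistic models with crossed random intercepts for fawn and year, VIF
# screening, alpha-based retention into an additive model, 5-fold
# squared-error cross-validation, and projection of the fitted model onto
# the landscape grid as a suitability surface.

RSF_COVARIATES <- c(LANDCOVER_CLASSES, "ndvi", "dist_road")

#' Assemble the use-availability table
#'
#' Pairs each retained radiolocation with one random point within the
#' availability radius, extracts buffered covariates for both, and stacks
#' them with the binomial response (1 = used, 0 = available).
#'
#' @param telemetry telemetry table (already error-filtered; see
#'   [filter_by_error()]).
#' @param landscape landscape list.
#' @param radius buffer radius (m).
#' @param avail_radius availability radius (m), the cumulative mean step
#'   length.
#' @param seed RNG seed for availability sampling.
#' @return data.frame: `fawn_id`, `year`, `response`, landcover proportion
#'   columns, `ndvi`, `risk_*`, `dist_road`.
#' @export
make_use_avail_table <- function(telemetry, landscape, radius = 26,
                                 avail_radius = 415, seed = 1) {
  ext <- raster_extent(landscape$landcover)
  avail <- sample_availability(telemetry, radius = avail_radius,
                               extent = c(ext["xmax"], ext["ymax"]),
                               seed = seed)
  used_buf <- extract_buffer(telemetry[, c("x", "y")], radius, landscape)
  avail_buf <- extract_buffer(avail, radius, landscape)
  ids <- telemetry[, c("fawn_id", "year")]
  out <- rbind(
    cbind(ids, response = 1L, used_buf[, setdiff(names(used_buf), c("x", "y"))]),
    cbind(ids, response = 0L, avail_buf[, setdiff(names(avail_buf), c("x", "y"))])
  )
  rownames(out) <- NULL
  out
}

#' Standardize covariates to z-scores
#'
#' Centres and scales the given columns over the pooled used + available
#' rows, retaining the scaler so fitted coefficients can be projected onto
#' grid-cell covariates later. Zero-variance covariates are dropped with a
#' warning.
#'
#' @param table a use-availability (or covariate) data.frame.
#' @param covariates column names to standardize.
#' @return list with `table` (covariate columns replaced by z-scores) and
#'   `scaler` (list of `mean` and `sd` named vectors).
#' @export
standardize <- function(table, covariates = RSF_COVARIATES) {
  covariates <- intersect(covariates, names(table))
  mu <- vapply(table[covariates], mean, numeric(1))
  sg <- vapply(table[covariates], sd, numeric(1))
  drop_cov <- covariates[!is.finite(sg) | sg <= 1e-12 * pmax(abs(mu), 1)]
  if (length(drop_cov)) {
    warning("dropping zero-variance covariate(s): ",
            paste(drop_cov, collapse = ", "))
    covariates <- setdiff(covariates, drop_cov)
    table <- table[, setdiff(names(table), drop_cov), drop = FALSE]
  }
  for (cv in covariates) table[[cv]] <- (table[[cv]] - mu[cv]) / sg[cv]
  list(table = table,
       scaler = list(mean = mu[covariates], sd = sg[covariates]))
}

#' Apply (or invert) a scaler
#' @param data data.frame with raw (or z-scored) covariate columns.
#' @param scaler scaler from [standardize()].
#' @param inverse if TRUE, map z-scores back to raw values.
#' @return data.frame with transformed columns.
#' @export
apply_scaler <- function(data, scaler, inverse = FALSE) {
  for (cv in names(scaler$mean)) {
    if (!cv %in% names(data)) next
    data[[cv]] <- if (inverse) {
      data[[cv]] * scaler$sd[cv] + scaler$mean[cv]
    } else {
      (data[[cv]] - scaler$mean[cv]) / scaler$sd[cv]
    }
  }
  data
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` from regressing covariate `k` on the others;
#' covariates at or above the threshold are flagged as collinear. Perfect
#' collinearity yields an infinite VIF (flagged, no error).
#'
#' @param table data.frame holding the covariates.
#' @param covariates covariate column names (>= 2).
#' @param threshold flag VIFs `>=` this value (default 7).
#' @return data.frame with `covariate`, `vif`, `flagged`.
#' @export
vif_screen <- function(table, covariates, threshold = 7) {
  covariates <- intersect(covariates, names(table))
  if (length(covariates) < 2) stop("need >= 2 covariates", call. = FALSE)
  X <- as.data.frame(table[covariates])
  vifs <- vapply(covariates, function(cv) {
    fit <- lm(reformulate(setdiff(covariates, cv), response = cv), data = X)
    r2 <- suppressWarnings(summary(fit)$r.squared) # perfect fits handled below
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = covariates, vif = unname(vifs),
             flagged = unname(vifs) >= threshold, row.names = NULL)
}

#' Fit a use-availability mixed logistic model
#'
#' Maximum-likelihood logistic regression of the used/available response on
#' standardized covariates, with crossed Gaussian random intercepts for
#' individual fawn and year (Laplace approximation via `lme4::glmer`).
#' With `random_effects = NULL` the model reduces to ordinary logistic
#' regression (`stats::glm`), the zero-variance special case.
#'
#' @param table standardized use-availability table.
#' @param covariates fixed-effect covariate names.
#' @param random_effects character vector of grouping columns (default
#'   `c("fawn_id", "year")`), or NULL for none.
#' @return object of class `rsf_fit`: coefficient table (estimate, SE, z,
#'   p), random-intercept variances, log-likelihood, and the underlying fit.
#' @export
fit_rsf <- function(table, covariates, random_effects = c("fawn_id", "year")) {
  stopifnot(all(covariates %in% names(table)))
  if (length(random_effects)) {
    if (length(unique(table$fawn_id)) < 2) {
      stop("need >= 2 fawns for random intercepts", call. = FALSE)
    }
    bars <- paste0("(1 | ", random_effects, ")")
    form <- reformulate(c(covariates, bars), response = "response")
    fit <- lme4::glmer(form, data = table, family = binomial,
                       control = lme4::glmerControl(calc.derivs = FALSE))
    if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
      stop(sprintf("glmer did not converge (optimizer code %d)",
                   fit@optinfo$conv$opt), call. = FALSE)
    }
    sm <- summary(fit)$coefficients
    vc <- lme4::VarCorr(fit)
    ranef_var <- vapply(random_effects, function(g) as.numeric(vc[[g]]),
                        numeric(1))
  } else {
    form <- reformulate(covariates, response = "response")
    fit <- glm(form, data = table, family = binomial)
    sm <- summary(fit)$coefficients
    ranef_var <- numeric(0)
  }
  coefs <- data.frame(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
    z = sm[, 3], p = sm[, 4], row.names = NULL
  )
  structure(list(
    covariates = covariates, random_effects = random_effects,
    coefficients = coefs, ranef_var = ranef_var,
    loglik = as.numeric(logLik(fit)), n = nrow(table),
    cv_error = NA_real_, fit = fit
  ), class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> %d rows, logLik %.2f, cv_error %s\n", x$n, x$loglik,
              ifelse(is.na(x$cv_error), "NA", sprintf("%.3f", x$cv_error))))
  print(x$coefficients, digits = 3)
  if (length(x$ranef_var)) {
    cat("random-intercept variances:",
        paste(sprintf("%s=%.4f", names(x$ranef_var), x$ranef_var),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# coefficient row for a single term of a fit
term_row <- function(fit, term) {
  fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
}

#' Retain individually significant covariates into an additive model
#'
#' Keeps every covariate whose single-covariate model has `p < alpha`
#' (strict; ties at alpha are excluded) and fits the additive model on the
#' retained set.
#'
#' @param single_fits named list of `rsf_fit`s, one per candidate covariate
#'   (names are the covariate names).
#' @param table standardized use-availability table.
#' @param alpha retention threshold (default 0.05).
#' @param random_effects passed to [fit_rsf()].
#' @return list with `retained` (covariate names), `p_values`, and `fit`
#'   (the additive `rsf_fit`).
#' @export
select_additive <- function(single_fits, table, alpha = 0.05,
                            random_effects = c("fawn_id", "year")) {
  p <- vapply(names(single_fits), function(cv) {
    term_row(single_fits[[cv]], cv)$p
  }, numeric(1))
  retained <- names(p)[p < alpha]
  if (!length(retained)) {
    stop("no covariate significant at alpha = ", alpha,
         "; no additive model can be formed (consider a larger candidate set",
         " or more data)", call. = FALSE)
  }
  fit <- fit_rsf(table, retained, random_effects)
  list(retained = retained, p_values = p, fit = fit)
}

#' k-fold squared-error prediction rate
#'
#' Partitions rows into `k` folds, trains an ordinary logistic regression on
#' k-1 folds, and scores the held-out rows; the reported error is the mean
#' squared difference between response and predicted probability (Brier
#' score) over all held-out rows. For a balanced table with an uninformative
#' covariate this converges to 0.25.
#'
#' @param table standardized use-availability table.
#' @param covariates model covariates.
#' @param k number of folds (>= 2).
#' @param seed RNG seed for fold assignment.
#' @param blocked if TRUE, assign whole fawns to folds rather than rows.
#' @return numeric cross-validation error in \[0, 1\].
#' @export
kfold_error <- function(table, covariates, k = 5, seed = 1, blocked = FALSE) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  set.seed(seed)
  n <- nrow(table)
  if (blocked) {
    fawns <- unique(table$fawn_id)
    ff <- sample(rep_len(seq_len(k), length(fawns)))
    fold <- ff[match(table$fawn_id, fawns)]
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  form <- reformulate(covariates, response = "response")
  sq_sum <- 0
  for (i in seq_len(k)) {
    train <- table[fold != i, , drop = FALSE]
    test <- table[fold == i, , drop = FALSE]
    m <- suppressWarnings(glm(form, data = train, family = binomial))
    p <- predict(m, newdata = test, type = "response")
    sq_sum <- sq_sum + sum((test$response - p)^2)
  }
  sq_sum / n
}

#' Project a fitted RSF onto the landscape grid
#'
#' Per-cell selection score `w = exp(sum_k beta_k z_k)` on z-scored cell
#' covariates (intercept and random effects excluded), then a linear
#' stretch to \[0, 1\]: cells near 1 have relatively greater likelihood of
#' being selected. An inverse-logit form is available; the two are
#' rank-equivalent after the stretch but not value-equivalent.
#'
#' @param fit an `rsf_fit` (typically the additive model).
#' @param scaler scaler from [standardize()].
#' @param grid a `landscape_grid`.
#' @param form `"exponential"` (default) or `"logistic"`.
#' @return object of class `risk_surface` with `kind = "suitability"`.
#' @export
suitability_surface <- function(fit, scaler, grid, form = c("exponential", "logistic")) {
  form <- match.arg(form)
  covs <- fit$covariates
  missing <- setdiff(covs, names(grid))
  if (length(missing)) {
    stop("grid lacks covariate column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  z <- apply_scaler(as.data.frame(grid)[covs], scaler)
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)[covs]
  lp <- as.numeric(as.matrix(z) %*% beta)
  w <- if (form == "exponential") exp(lp) else plogis(lp)
  new_risk_surface(grid, linear_stretch(w), kind = "suitability",
                   provenance = paste0("rsf:", form))
}

#' Construct a risk surface bound to a grid
#' @param grid a `landscape_grid`.
#' @param values per-cell values (grid row order).
#' @param kind one of `"suitability"`, `"composite_risk"`, `"mortality"`.
#' @param provenance free-text provenance tag.
#' @return object of class `risk_surface`.
#' @export
new_risk_surface <- function(grid, values,
                             kind = c("suitability", "composite_risk", "mortality"),
                             provenance = "") {
  kind <- match.arg(kind)
  stopifnot(length(values) == nrow(grid))
  structure(list(
    values = as.numeric(values), kind = kind, provenance = provenance,
    n_rows = attr(grid, "n_rows"), n_cols = attr(grid, "n_cols"),
    cellsize = attr(grid, "cellsize"), origin = attr(grid, "origin")
  ), class = "risk_surface")
}

#' @export
print.risk_surface <- function(x, ...) {
  cat(sprintf("<risk_surface:%s> %d x %d cells, range [%.3f, %.3f] (%s)\n",
              x$kind, x$n_rows, x$n_cols, min(x$values), max(x$values),
              x$provenance))
  invisible(x)
}

#' Convert a risk surface to a raster
#' @param surface a `risk_surface`.
#' @return an `fs_raster`.
#' @export
surface_to_raster <- function(surface) {
  m <- matrix(surface$values, nrow = surface$n_rows, ncol = surface$n_cols,
              byrow = TRUE)
  fs_raster(m, xmin = surface$origin[1], ymin = surface$origin[2],
            cellsize = surface$cellsize)
}
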