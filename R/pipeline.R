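# End-to-end orchestration: simulate -> rsf -> covariates -> survival ->
# surfaces, with a manifest recording versions, seeds and option values so
# a run is reproducible from its output directory alone.

#' Pipeline configuration
#'
#' Bundles the simulation configuration with the analysis options. Unknown
#' option names are rejected.
#'
#' @param sim a [sim_config()].
#' @param ... analysis options overriding the defaults: `alpha` (RSF
#'   retention threshold), `k` (CV folds), `buffer_radius` (m),
#'   `avail_radius` (m), `cell_area` (m^2), `error_threshold` (m^2),
#'   `rsf_form` ("exponential"/"logistic"), `severity_convention`
#'   ("severity"/"literal"), `birth_mass_mode` ("per_day"/"literal"),
#'   `random_effects` (frailty groupings), `cv_blocked` (logical).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), ...) {
  stopifnot(inherits(sim, "sim_config"))
  opts <- list(
    alpha = 0.05, k = 5L, buffer_radius = 26, avail_radius = 415,
    cell_area = 2115, error_threshold = sim$mean_ellipse_area,
    rsf_form = "exponential", severity_convention = "severity",
    birth_mass_mode = "per_day", random_effects = c("fawn_id", "year"),
    cv_blocked = FALSE
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(opts))
  if (length(unknown)) {
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  opts[names(extra)] <- extra
  for (nm in c("alpha", "k", "buffer_radius", "avail_radius", "cell_area",
               "error_threshold")) {
    if (opts[[nm]] <= 0) stop(nm, " must be positive", call. = FALSE)
  }
  structure(list(sim = sim, opts = opts), class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order on a synthetic world drawn from
#' the configuration, writing per-stage artifacts and a JSON run manifest
#' under `out_dir`. Stage outputs are also returned for interactive use.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); NULL to skip all
#'   file output.
#' @param stages subset of `c("simulate", "rsf", "covariates", "survival",
#'   "surfaces")`; later stages require earlier ones in the same call.
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         stages = c("simulate", "rsf", "covariates",
                                    "survival", "surfaces"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "rsf", "covariates", "survival", "surfaces")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  need <- all_stages[seq_len(max(match(stages, all_stages)))]
  if (!all(need %in% stages)) {
    stop("stages must be a prefix of the pipeline: ",
         paste(need, collapse = " -> "), call. = FALSE)
  }
  log_line <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[fawnsurv] ", fmt), ...))
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  opts <- config$opts
  res <- list()

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------------
  run_stage("simulate", function() {
    log_line("simulate: landscape %g x %g m, %d fawns, %d years",
             sim$extent[1], sim$extent[2], sim$n_fawns, sim$n_years)
    landscape <- generate_landscape(sim)
    weather <- generate_weather(sim)
    fawns <- generate_fawns(sim, weather)
    telemetry <- generate_telemetry(sim, landscape, fawns)
    grid <- build_grid(landscape, cell_area = opts$cell_area)

    # true per-fawn covariates under the configured selection coefficients,
    # used only to draw fates; the analysis stages refit from data
    true_cov <- names(sim$true_rsf_betas)
    gz <- standardize(as.data.frame(grid), intersect(true_cov, names(grid)))
    beta <- sim$true_rsf_betas[names(gz$scaler$mean)]
    lp <- as.matrix(gz$table[names(beta)]) %*% beta
    true_suit <- new_risk_surface(grid, linear_stretch(exp(drop(lp))),
                                  kind = "suitability", provenance = "true betas")
    fc <- suppressWarnings(fawn_covariates(
      filter_by_error(telemetry, opts$error_threshold), true_suit, grid,
      landscape, weather, fawns, radius = opts$buffer_radius,
      severity_convention = opts$severity_convention,
      birth_mass_mode = opts$birth_mass_mode))
    fates <- generate_fates(sim, fc$table)
    res$simulate <<- list(landscape = landscape, weather = weather,
                          fawns = fawns, telemetry = telemetry, grid = grid,
                          fates = fates)
    if (!is.null(out_dir)) {
      sd <- file.path(out_dir, "simulate")
      write_landscape(landscape, sd)
      write.csv(weather, file.path(sd, "weather.csv"), row.names = FALSE)
      write.csv(fawns, file.path(sd, "fawns.csv"), row.names = FALSE)
      write.csv(telemetry, file.path(sd, "telemetry.csv"), row.names = FALSE)
      write.csv(fates, file.path(sd, "fates.csv"), row.names = FALSE)
    }
  })
  if (identical(stages, "simulate")) {
    return(invisible(finish_manifest(res, config, out_dir, stages, quiet)))
  }

  # -- rsf -----------------------------------------------------------------
  run_stage("rsf", function() {
    s <- res$simulate
    telem <- filter_by_error(s$telemetry, opts$error_threshold)
    ua <- make_use_avail_table(telem, s$landscape,
                               radius = opts$buffer_radius,
                               avail_radius = opts$avail_radius,
                               seed = sim$seed + 10L)
    candidates <- c(setdiff(s$landscape$class_names, "other"), "dist_road")
    std <- standardize(ua, candidates)
    candidates <- intersect(candidates, names(std$scaler$mean))
    vif <- vif_screen(std$table, candidates)
    candidates <- vif$covariate[!vif$flagged]
    log_line("rsf: %d candidate covariates after VIF screen, %d rows",
             length(candidates), nrow(ua))
    singles <- lapply(candidates, function(cv) {
      fit <- fit_rsf(std$table, cv, opts$random_effects)
      fit$cv_error <- kfold_error(std$table, cv, k = opts$k,
                                  seed = sim$seed + 20L,
                                  blocked = opts$cv_blocked)
      fit
    })
    names(singles) <- candidates
    add <- select_additive(singles, std$table, alpha = opts$alpha,
                           random_effects = opts$random_effects)
    add$fit$cv_error <- kfold_error(std$table, add$retained, k = opts$k,
                                    seed = sim$seed + 20L,
                                    blocked = opts$cv_blocked)
    suit <- suitability_surface(add$fit, std$scaler, s$grid,
                                form = opts$rsf_form)
    tab2 <- do.call(rbind, lapply(candidates, function(cv) {
      tr <- term_row(singles[[cv]], cv)
      data.frame(parameter = cv, coefficient = tr$estimate,
                 standard_error = tr$se, z_value = tr$z, p_value = tr$p,
                 prediction_error = singles[[cv]]$cv_error, row.names = NULL)
    }))
    res$rsf <<- list(use_avail = std$table, scaler = std$scaler, vif = vif,
                     singles = singles, additive = add, suitability = suit,
                     table = tab2)
    if (!is.null(out_dir)) {
      rd <- file.path(out_dir, "rsf")
      dir.create(rd, showWarnings = FALSE, recursive = TRUE)
      write.csv(tab2, file.path(rd, "rsf_models.csv"), row.names = FALSE)
      write.csv(vif, file.path(rd, "vif.csv"), row.names = FALSE)
      write.csv(as.data.frame(s$grid), file.path(rd, "grid.csv"),
                row.names = FALSE)
      write_asc(surface_to_raster(suit), file.path(rd, "suitability.asc"))
    }
  })
  if (!"covariates" %in% stages) {
    return(invisible(finish_manifest(res, config, out_dir, stages, quiet)))
  }

  # -- covariates ----------------------------------------------------------
  run_stage("covariates", function() {
    s <- res$simulate
    telem <- filter_by_error(s$telemetry, opts$error_threshold)
    fc <- fawn_covariates(telem, res$rsf$suitability, s$grid, s$landscape,
                          s$weather, s$fawns, radius = opts$buffer_radius,
                          severity_convention = opts$severity_convention,
                          birth_mass_mode = opts$birth_mass_mode)
    log_line("covariates: %d fawns with covariates", nrow(fc$table))
    res$covariates <<- fc
    if (!is.null(out_dir)) {
      cd <- file.path(out_dir, "covariates")
      dir.create(cd, showWarnings = FALSE, recursive = TRUE)
      write.csv(fc$table, file.path(cd, "fawn_covariates.csv"),
                row.names = FALSE)
    }
  })
  if (!"survival" %in% stages) {
    return(invisible(finish_manifest(res, config, out_dir, stages, quiet)))
  }

  # -- survival ------------------------------------------------------------
  run_stage("survival", function() {
    fc <- res$covariates
    fates <- res$simulate$fates
    records <- merge(fc$table,
                     fates[, c("fawn_id", "stop_day", "event")],
                     by = "fawn_id", sort = TRUE)
    ranking <- run_model_set(records, random_effects = opts$random_effects)
    log_line("survival: %d models ranked; top = '%s' (DE %.2f)",
             length(ranking$fits), ranking$summary$model[1],
             ranking$summary$deviance_explained[1])
    res$survival <<- list(records = records, ranking = ranking)
    if (!is.null(out_dir)) {
      vd <- file.path(out_dir, "survival")
      dir.create(vd, showWarnings = FALSE, recursive = TRUE)
      write.csv(ranking$report, file.path(vd, "cox_models.csv"),
                row.names = FALSE)
      base <- do.call(rbind, lapply(names(ranking$fits), function(nm) {
        cbind(model = nm, ranking$fits[[nm]]$baseline)
      }))
      write.csv(base, file.path(vd, "baseline_survival.csv"),
                row.names = FALSE)
    }
  })
  if (!"surfaces" %in% stages) {
    return(invisible(finish_manifest(res, config, out_dir, stages, quiet)))
  }

  # -- surfaces ------------------------------------------------------------
  run_stage("surfaces", function() {
    s <- res$simulate
    grid <- s$grid
    # spatial covariates on the grid, raw scale, named as the survival terms
    grid2 <- transform_grid(grid,
                            resource_use = res$rsf$suitability$values,
                            predation_risk = composite_risk(grid))
    fit <- res$survival$ranking$fits[["Non-ideal resource use"]]
    mort <- mortality_surface(fit, grid2, res$covariates$scaler)
    comp <- composite_risk_surface(grid)
    panel <- surface_panel(res$rsf$suitability, comp, mort, grid,
                           dir = if (is.null(out_dir)) NULL else
                             file.path(out_dir, "surfaces"))
    log_line("surfaces: wrote suitability / composite risk / mortality panel")
    res$surfaces <<- list(suitability = res$rsf$suitability,
                          composite = comp, mortality = mort, panel = panel)
  })

  invisible(finish_manifest(res, config, out_dir, stages, quiet))
}

finish_manifest <- function(res, config, out_dir, stages, quiet) {
  manifest <- list(
    package = "fawnsurv",
    version = as.character(utils::packageVersion("fawnsurv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$sim$seed,
    stages = stages,
    options = config$opts[setdiff(names(config$opts), "random_effects")],
    random_effects = config$opts$random_effects,
    sim = list(
      extent = config$sim$extent, n_classes = config$sim$n_classes,
      n_fawns = config$sim$n_fawns, n_years = config$sim$n_years,
      mean_step = config$sim$mean_step,
      mean_ellipse_area = config$sim$mean_ellipse_area
    )
  )
  if (!is.null(out_dir)) {
    files <- sort(setdiff(
      list.files(out_dir, recursive = TRUE),
      "manifest.json"
    ))
    manifest$artifacts <- lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res$manifest <- manifest
  res
}
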