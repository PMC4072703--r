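# The candidate model set: twelve proportional-hazards models encoding the
# competing predictions (ideal vs non-ideal resource use, ecological trap,
# maternal effects, hiding cover), all with fawn and year frailties, ranked
# by deviance explained relative to the random-effects-only null.

#' The twelve-model candidate set
#'
#' Named list mapping model labels to their fixed-effect term vectors.
#' `resource_use` is the fawn's mean resource suitability,
#' `predation_risk` the mean composite multi-predator risk, `birth_mass`
#' the back-calculated birth mass, `winter_severity` the year-level winter
#' severity index, and `veg_growth` the mean vegetation growth (hiding
#' cover); all z-scored.
#'
#' @return named list of character vectors.
#' @export
cox_model_set <- function() {
  list(
    "Non-ideal resource use + Maternal effects" = c(
      "resource_use", "predation_risk", "birth_mass", "winter_severity",
      "birth_mass:winter_severity"),
    "Maternal effects" = c(
      "birth_mass", "winter_severity", "birth_mass:winter_severity"),
    "Ecological trap + Maternal effects" = c(
      "resource_use", "predation_risk", "resource_use:predation_risk",
      "birth_mass", "winter_severity", "birth_mass:winter_severity"),
    "Body mass" = "birth_mass",
    "Ecological trap + Hiding cover" = c(
      "resource_use", "predation_risk", "resource_use:predation_risk",
      "veg_growth"),
    "Ecological trap" = c(
      "resource_use", "predation_risk", "resource_use:predation_risk"),
    "Non-ideal resource use + Hiding cover" = c(
      "resource_use", "predation_risk", "veg_growth"),
    "Resource use" = "resource_use",
    "Non-ideal resource use" = c("resource_use", "predation_risk"),
    "Predation risk" = "predation_risk",
    "Winter severity index" = "winter_severity",
    "Hiding cover" = "veg_growth"
  )
}

#' Fit and rank the candidate model set
#'
#' Fits the random-effects-only null and every model in [cox_model_set()]
#' (models whose covariates are absent from the records are skipped with a
#' warning), computes deviance explained and the likelihood-ratio
#' chi-square against the null, and ranks models by deviance explained.
#'
#' @param records standardized survival records (see [fit_cox()]).
#' @param random_effects frailty groupings, default `c("fawn_id", "year")`.
#' @param models optional named list of term vectors overriding the default
#'   set.
#' @return object of class `cox_model_ranking`: `fits` (named list, ranked),
#'   `null` (the null fit), `summary` (one row per model: deviance
#'   explained, LR chi-square and p), `report` (long-format table with one
#'   row per coefficient, mirroring the standard report layout).
#' @export
run_model_set <- function(records, random_effects = c("fawn_id", "year"),
                          models = cox_model_set()) {
  null_fit <- fit_cox(records, character(0), random_effects,
                      model_name = "(null)")
  fits <- list()
  for (nm in names(models)) {
    mains <- unique(unlist(strsplit(models[[nm]], ":", fixed = TRUE)))
    if (!all(mains %in% names(records))) {
      warning("skipping model '", nm, "': missing covariate(s) ",
              paste(setdiff(mains, names(records)), collapse = ", "))
      next
    }
    fits[[nm]] <- fit_cox(records, models[[nm]], random_effects,
                          model_name = nm)
  }
  des <- lapply(fits, deviance_explained, null_fit = null_fit)
  summary <- data.frame(
    model = names(fits),
    n_terms = vapply(fits, function(f) f$n_terms, integer(1)),
    df = vapply(fits, function(f) f$df, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    deviance_explained = vapply(des, `[[`, numeric(1), "deviance_explained"),
    lr_chisq = vapply(des, `[[`, numeric(1), "lr_chisq"),
    lr_p = vapply(des, `[[`, numeric(1), "lr_p"),
    row.names = NULL
  )
  ord <- order(summary$deviance_explained, decreasing = TRUE)
  summary <- summary[ord, , drop = FALSE]
  rownames(summary) <- NULL
  fits <- fits[summary$model]

  report <- do.call(rbind, lapply(summary$model, function(nm) {
    f <- fits[[nm]]
    s <- summary[summary$model == nm, ]
    cf <- f$coefficients
    data.frame(
      model = nm, term = cf$term, estimate = cf$estimate, se = cf$se,
      p = cf$p, hazard_ratio = cf$hazard_ratio, df = s$df,
      deviance_explained = s$deviance_explained, lr_chisq = s$lr_chisq,
      lr_p = s$lr_p, row.names = NULL
    )
  }))

  structure(list(fits = fits, null = null_fit, summary = summary,
                 report = report),
            class = "cox_model_ranking")
}

#' @export
print.cox_model_ranking <- function(x, ...) {
  cat(sprintf("<cox_model_ranking> %d models, null logLik %.3f\n",
              length(x$fits), x$null$loglik))
  print(x$summary, digits = 4)
  invisible(x)
}
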