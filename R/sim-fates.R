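# Fate generator: death times from a proportional-hazards model with
# Gaussian fawn- and year-level frailties on the log-hazard scale, plus two
# lightweight distributional simulators used by the parameter-recovery test
# suites (mixed logistic use-availability data; frailty survival data).

#' Generate fawn fates from a proportional-hazards model
#'
#' Death times are drawn from `h(t) = h0 * exp(X beta + b_fawn + b_year)`
#' with a constant baseline hazard `h0` and Gaussian frailties, then
#' administratively censored at the end of the monitoring season (each
#' fawn's follow-up runs from birth to `season_length`). Causes of death are
#' assigned with the predator mix observed in the study system (coyote 47%,
#' bobcat 23%, black bear 8%, wolf 8%, unknown 14%).
#'
#' @param config a [sim_config()].
#' @param covariates data.frame with one row per fawn: `fawn_id`, `year`,
#'   `birth_date`, plus z-scored columns named by the main effects appearing
#'   in `config$true_cox_betas` (interaction terms `a:b` are formed
#'   internally).
#' @return data.frame of fawn records: `fawn_id`, `year`, `birth_date`,
#'   `stop_day` (days since birth), `event` (1 death / 0 censored), `cause`.
#' @export
generate_fates <- function(config, covariates) {
  stopifnot(inherits(config, "sim_config"))
  if (config$baseline_hazard < 0 || config$frailty_sd_fawn < 0 ||
      config$frailty_sd_year < 0) {
    stop("hazard parameters must be non-negative", call. = FALSE)
  }
  need <- c("fawn_id", "year", "birth_date")
  if (!all(need %in% names(covariates))) {
    stop("covariates must carry fawn_id, year and birth_date", call. = FALSE)
  }
  set.seed(config$seed + 4L)
  n <- nrow(covariates)
  betas <- config$true_cox_betas
  X <- build_term_matrix(covariates, names(betas))
  b_f <- rnorm(n, 0, config$frailty_sd_fawn)
  yrs <- sort(unique(covariates$year))
  b_y <- rnorm(length(yrs), 0, config$frailty_sd_year)
  lp <- drop(X %*% betas) + b_f + b_y[match(covariates$year, yrs)]
  rate <- config$baseline_hazard * exp(lp)
  t_death <- ifelse(rate > 0, rexp(n) / pmax(rate, .Machine$double.xmin), Inf)
  follow <- pmax(1, config$season_length - covariates$birth_date)
  event <- as.integer(t_death <= follow)
  stop_day <- pmax(1e-8, pmin(t_death, follow))
  cause <- rep("censored", n)
  if (any(event == 1)) {
    cause[event == 1] <- sample(
      c("coyote", "bobcat", "black_bear", "wolf", "unknown"),
      sum(event), replace = TRUE,
      prob = c(0.47, 0.23, 0.08, 0.08, 0.14)
    )
  }
  data.frame(
    fawn_id = covariates$fawn_id, year = covariates$year,
    birth_date = covariates$birth_date,
    stop_day = stop_day, event = event, cause = cause
  )
}

# Expand term labels (main effects and "a:b" interactions) against a
# data.frame of main-effect columns into a numeric model matrix, no
# intercept.
build_term_matrix <- function(data, terms) {
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    missing <- setdiff(parts, names(data))
    if (length(missing)) {
      stop("missing covariate column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    Reduce(`*`, lapply(parts, function(p) as.numeric(data[[p]])))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

#' Simulate use-availability data from the mixed logistic model
#'
#' Draws covariates as standard normals and responses from
#' `Bernoulli(plogis(X beta + b_fawn + b_year))` with Gaussian random
#' intercepts. This is the distributional harness for testing that the
#' resource-selection fitter recovers known coefficients with nominal
#' confidence-interval coverage; it deliberately generates from exactly the
#' model the fitter assumes.
#'
#' @param n_fawns,locs_per_fawn design size (rows = n_fawns * locs_per_fawn).
#' @param betas named numeric vector of true coefficients.
#' @param sd_fawn,sd_year random-intercept SDs.
#' @param n_years number of year levels.
#' @param intercept fixed intercept (default 0, balanced design).
#' @param seed RNG seed.
#' @return data.frame with `fawn_id`, `year`, `response` and one column per
#'   name of `betas`.
#' @export
simulate_use_avail <- function(n_fawns, locs_per_fawn, betas,
                               sd_fawn = 0.3, sd_year = 0.3, n_years = 3,
                               intercept = 0, seed = 1) {
  set.seed(seed)
  n <- n_fawns * locs_per_fawn
  fawn <- rep(seq_len(n_fawns), each = locs_per_fawn)
  year <- rep(rep_len(seq_len(n_years), n_fawns), each = locs_per_fawn)
  X <- matrix(rnorm(n * length(betas)), n, length(betas),
              dimnames = list(NULL, names(betas)))
  b_f <- rnorm(n_fawns, 0, sd_fawn)
  b_y <- rnorm(n_years, 0, sd_year)
  eta <- intercept + drop(X %*% betas) + b_f[fawn] + b_y[year]
  out <- data.frame(
    fawn_id = sprintf("F%04d", fawn), year = year,
    response = rbinom(n, 1, plogis(eta))
  )
  cbind(out, as.data.frame(X))
}

#' Simulate survival records from the frailty proportional-hazards model
#'
#' Standard-normal covariates, constant baseline hazard, Gaussian fawn and
#' year frailties, administrative censoring at `follow_up` days. Used by the
#' survival-module recovery suites.
#'
#' @param n_fawns number of subjects.
#' @param betas named numeric vector of log-hazard coefficients (interaction
#'   labels `a:b` allowed; main effects are drawn).
#' @param h0 constant baseline hazard (per day).
#' @param sd_fawn,sd_year frailty SDs.
#' @param n_years number of year levels.
#' @param follow_up administrative censoring time (days).
#' @param seed RNG seed.
#' @return data.frame with `fawn_id`, `year`, `stop_day`, `event` and the
#'   main-effect covariate columns.
#' @export
simulate_survival <- function(n_fawns, betas, h0 = 0.006,
                              sd_fawn = 0.3, sd_year = 0.3, n_years = 3,
                              follow_up = 109, seed = 1) {
  set.seed(seed)
  mains <- unique(unlist(strsplit(names(betas), ":", fixed = TRUE)))
  X <- matrix(rnorm(n_fawns * length(mains)), n_fawns, length(mains),
              dimnames = list(NULL, mains))
  df <- as.data.frame(X)
  M <- build_term_matrix(df, names(betas))
  year <- rep_len(seq_len(n_years), n_fawns)
  lp <- drop(M %*% betas) + rnorm(n_fawns, 0, sd_fawn) +
    rnorm(n_years, 0, sd_year)[year]
  rate <- h0 * exp(lp)
  t_death <- ifelse(rate > 0, rexp(n_fawns) / pmax(rate, .Machine$double.xmin), Inf)
  event <- as.integer(t_death <= follow_up)
  data.frame(
    fawn_id = sprintf("F%04d", seq_len(n_fawns)), year = year,
    stop_day = pmin(t_death, follow_up), event = event
  ) |> cbind(df)
}
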