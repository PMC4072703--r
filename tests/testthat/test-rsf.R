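# Resource-selection module: standardization, VIF, mixed logistic fits,
# additive selection, cross-validation, and the suitability surface.

test_that("standardize centres, scales, round-trips, and drops constants", {
  set.seed(4)
  tab <- data.frame(a = rnorm(200, 5, 3), b = runif(200), c = 1)
  expect_warning(std <- standardize(tab, c("a", "b", "c")), "zero-variance")
  expect_equal(mean(std$table$a), 0, tolerance = 1e-9)
  expect_equal(sd(std$table$a), 1, tolerance = 1e-9)
  expect_equal(mean(std$table$b), 0, tolerance = 1e-9)
  expect_false("c" %in% names(std$table))

  # inverse transform recovers raw values
  back <- apply_scaler(std$table, std$scaler, inverse = TRUE)
  expect_equal(back$a, tab$a, tolerance = 1e-9)
  expect_equal(back$b, tab$b, tolerance = 1e-9)

  # idempotence: standardizing an already-standardized table changes nothing
  std2 <- standardize(std$table, c("a", "b"))
  expect_equal(std2$table$a, std$table$a, tolerance = 1e-9)

  # z-scores invariant to affine rescaling of the raw covariate
  tab2 <- tab; tab2$a <- 3 * tab$a + 7
  std3 <- standardize(tab2, c("a", "b"))
  expect_equal(std3$table$a, std$table$a, tolerance = 1e-9)
})

test_that("VIF has closed-form values on constructed designs", {
  n <- 400
  set.seed(8)
  # columns orthogonal to each other AND to the intercept (centred), so the
  # auxiliary regressions have R^2 exactly 0 -> VIF exactly 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  tab <- as.data.frame(Q)
  names(tab) <- c("u", "v", "w")
  vif <- vif_screen(tab, c("u", "v", "w"))
  expect_equal(vif$vif, rep(1, 3), tolerance = 1e-9)
  expect_false(any(vif$flagged))

  # sample correlation exactly 0.9 -> VIF = 1/(1-0.81)
  x1 <- Q[, 1]; x2 <- 0.9 * Q[, 1] + sqrt(1 - 0.81) * Q[, 2]
  tab2 <- data.frame(x1 = x1, x2 = x2)
  vif2 <- vif_screen(tab2, c("x1", "x2"))
  expect_equal(vif2$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-9)
  expect_false(any(vif2$flagged))

  # duplicated covariate -> infinite VIF, flagged, no crash
  tab3 <- data.frame(x1 = x1, x2 = x1, x3 = Q[, 3])
  vif3 <- vif_screen(tab3, c("x1", "x2", "x3"))
  expect_true(all(is.infinite(vif3$vif[1:2])))
  expect_true(all(vif3$flagged[1:2]))
  expect_error(vif_screen(tab3, "x1"), ">= 2")
})

test_that("fit_rsf without random effects equals the glm oracle", {
  d <- simulate_use_avail(30, 20, c(x1 = -0.6, x2 = 0.3),
                          sd_fawn = 0, sd_year = 0, seed = 5)
  fit <- fit_rsf(d, c("x1", "x2"), random_effects = NULL)
  oracle <- glm(response ~ x1 + x2, data = d, family = binomial)
  expect_equal(
    setNames(fit$coefficients$estimate, fit$coefficients$term),
    coef(oracle), tolerance = 1e-6
  )
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-8)
})

test_that("mixed fit recovers coefficients and random-intercept variances", {
  d <- simulate_use_avail(150, 25, c(x1 = -0.6), sd_fawn = 0.5,
                          sd_year = 0.3, n_years = 5, seed = 6)
  fit <- fit_rsf(d, "x1")
  b <- fit$coefficients[fit$coefficients$term == "x1", ]
  expect_lt(abs(b$estimate - (-0.6)), 3 * b$se)
  expect_named(fit$ranef_var, c("fawn_id", "year"))
  expect_gt(fit$ranef_var[["fawn_id"]], 0.05)
  expect_error(fit_rsf(d[d$fawn_id == d$fawn_id[1], ], "x1"), ">= 2 fawns")
})

test_that("additive selection applies the strict alpha rule", {
  # single-covariate p-value pattern from a nine-candidate screen: the three
  # non-significant candidates are dropped, the six significant retained
  p_pattern <- c(lowland_forest = 1e-4, deciduous_forest = 0.043,
                 coniferous_forest = 1e-4, mixed_forest = 0.774,
                 grass_shrub = 0.830, pasture = 0.003, cropland = 0.397,
                 wetland = 0.022, dist_road = 1e-6)
  set.seed(10)
  n <- 300
  tab <- as.data.frame(matrix(rnorm(n * 9), n, 9,
                              dimnames = list(NULL, names(p_pattern))))
  tab$response <- rbinom(n, 1, 0.5)
  tab$fawn_id <- rep(1:30, each = 10)
  tab$year <- rep(1:3, 100)
  singles <- lapply(names(p_pattern), function(cv) {
    f <- fit_rsf(tab, cv, random_effects = NULL)
    f$coefficients$p[f$coefficients$term == cv] <- p_pattern[[cv]]
    f
  })
  names(singles) <- names(p_pattern)
  sel <- select_additive(singles, tab, alpha = 0.05, random_effects = NULL)
  expect_setequal(sel$retained,
                  c("lowland_forest", "deciduous_forest", "coniferous_forest",
                    "pasture", "wetland", "dist_road"))
  expect_s3_class(sel$fit, "rsf_fit")

  # ties at alpha are excluded (strict <)
  singles2 <- singles
  singles2$deciduous_forest$coefficients$p[
    singles2$deciduous_forest$coefficients$term == "deciduous_forest"] <- 0.05
  sel2 <- select_additive(singles2, tab, random_effects = NULL)
  expect_false("deciduous_forest" %in% sel2$retained)

  # nothing significant -> error with guidance
  singles3 <- lapply(singles, function(f) {
    f$coefficients$p <- pmax(f$coefficients$p, 0.9); f
  })
  expect_error(select_additive(singles3, tab, random_effects = NULL),
               "no covariate significant")
})

test_that("k-fold error is ~0.25 for noise and small for separation", {
  set.seed(12)
  n <- 3000
  tab <- data.frame(response = rep(0:1, n / 2), x = rnorm(n),
                    fawn_id = rep(1:100, each = n / 100))
  cv <- kfold_error(tab, "x", k = 5, seed = 3)
  expect_lt(abs(cv - 0.25), 0.01)
  # reproducible and fold-partitioning
  expect_identical(cv, kfold_error(tab, "x", k = 5, seed = 3))
  expect_false(identical(cv, kfold_error(tab, "x", k = 5, seed = 4)))

  # a perfectly separating covariate predicts almost certainly
  tab$z <- tab$response * 2 - 1 + rnorm(n, 0, 0.05)
  expect_lt(suppressWarnings(kfold_error(tab, "z", k = 5, seed = 3)), 0.05)

  # the true model beats a noise-only model
  tab$good <- tab$response * 1.2 + rnorm(n)
  expect_lt(kfold_error(tab, "good", k = 5, seed = 3), cv)

  expect_error(kfold_error(tab, "x", k = 1), "k must be")

  # fawn-blocked folds keep whole fawns together
  cvb <- kfold_error(tab, "x", k = 5, seed = 3, blocked = TRUE)
  expect_lt(abs(cvb - 0.25), 0.01)
})

test_that("Wald p-values are uniform under the null", {
  set.seed(14)
  pvals <- replicate(400, {
    n <- 150
    d <- data.frame(response = rep(0:1, n / 2), x = rnorm(n))
    f <- suppressWarnings(fit_rsf(d, "x", random_effects = NULL))
    f$coefficients$p[f$coefficients$term == "x"]
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("suitability surface is monotone in a single covariate", {
  w <- tiny_world()
  grid <- build_grid(w$landscape)
  fit <- structure(list(
    covariates = "dist_road",
    coefficients = data.frame(term = "dist_road", estimate = -0.6,
                              se = 0.1, z = -6, p = 0)
  ), class = "rsf_fit")
  scaler <- list(mean = c(dist_road = mean(grid$dist_road)),
                 sd = c(dist_road = sd(grid$dist_road)))
  surf <- suitability_surface(fit, scaler, grid)
  expect_s3_class(surf, "risk_surface")
  expect_equal(surf$kind, "suitability")
  # ranking strictly decreasing in distance to road
  expect_equal(order(surf$values), order(-grid$dist_road))
  expect_equal(min(surf$values), 0)
  expect_equal(max(surf$values), 1)

  # exponential and logistic forms are rank-equivalent
  surf2 <- suitability_surface(fit, scaler, grid, form = "logistic")
  expect_equal(order(surf2$values), order(surf$values))

  # all-zero coefficients -> degenerate stretch
  fit0 <- fit
  fit0$coefficients$estimate <- 0
  expect_warning(s0 <- suitability_surface(fit0, scaler, grid), "degenerate")
  expect_true(all(s0$values == 0))

  # missing grid covariate -> schema error
  fit_bad <- fit
  fit_bad$covariates <- "nonexistent"
  expect_error(suitability_surface(fit_bad, scaler, grid), "nonexistent")
})

test_that("use-availability tables pair one available point per location", {
  w <- tiny_world()
  tel <- filter_by_error(w$telemetry, 2115)
  tel <- tel[1:200, ]
  ua <- make_use_avail_table(tel, w$landscape, seed = 77)
  expect_equal(nrow(ua), 400)
  expect_equal(sum(ua$response), 200)
  expect_equal(ua$fawn_id[ua$response == 1], ua$fawn_id[ua$response == 0])
  props <- as.matrix(ua[, w$landscape$class_names])
  expect_equal(unname(rowSums(props)), rep(1, 400), tolerance = 1e-9)
  expect_identical(ua, make_use_avail_table(tel, w$landscape, seed = 77))
})
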