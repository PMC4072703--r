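# Synthetic-data generators: determinism, calibration targets, and the
# distributional contracts the downstream fitters rely on.

test_that("sim_config validates its invariants", {
  expect_error(sim_config(extent = c(-1, 100)), "extent")
  expect_error(sim_config(frailty_sd_fawn = -0.1), "SD")
  expect_error(sim_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(sim_config(class_targets = c(a = 0.5, b = 0.6), n_classes = 2,
                          other_frac = 0.08), "sum to 1")
})

test_that("landscape generation is deterministic and hits class targets", {
  cfg <- tiny_config()
  l1 <- generate_landscape(cfg)
  l2 <- generate_landscape(cfg)
  expect_identical(l1$landcover$values, l2$landcover$values)
  expect_identical(l1$ndvi$values, l2$ndvi$values)
  expect_identical(l1$roads$lines, l2$roads$lines)
  expect_identical(l1$predators$wolf$values, l2$predators$wolf$values)

  # realized proportions within 2 percentage points of targets (10% cropland)
  realized <- tabulate(l1$landcover$values, length(l1$class_names)) /
    length(l1$landcover$values)
  names(realized) <- l1$class_names
  expect_lt(abs(realized[["cropland"]] - 0.10), 0.02)
  targets <- c(cfg$class_targets, other = cfg$other_frac)
  expect_true(all(abs(realized[names(targets)] - targets) < 0.02))

  # predator surfaces smooth and in [0, 1]
  for (sp in names(l1$predators)) {
    v <- l1$predators[[sp]]$values
    expect_true(all(v >= 0 & v <= 1))
  }
  # road density near its target
  dens <- roads_length(l1$roads) / 1000 / (prod(cfg$extent) / 1e6)
  expect_gt(dens, cfg$road_density * 0.95)
  expect_lt(dens, cfg$road_density * 1.6) # last chord can overshoot
})

test_that("single-class config yields a uniform raster", {
  cfg <- sim_config(seed = 2, extent = c(600, 600), n_classes = 1)
  l <- generate_landscape(cfg)
  expect_equal(unique(as.numeric(l$landcover$values)), 1)
})

test_that("non-positive extent errors", {
  cfg <- tiny_config()
  cfg$extent <- c(0, 1000)
  expect_error(generate_landscape(cfg), "extent")
})

test_that("telemetry has per-fawn counts in [2, 56] and calibrated steps", {
  cfg <- sim_config(seed = 5, extent = c(8000, 8000), n_fawns = 110,
                    n_years = 3)
  landscape <- generate_landscape(cfg)
  fawns <- generate_fawns(cfg)
  tel <- generate_telemetry(cfg, landscape, fawns)
  counts <- table(tel$fawn_id)
  expect_true(all(counts >= 2 & counts <= 56))
  expect_equal(length(counts), 110)

  steps <- unlist(lapply(split(tel, tel$fawn_id), function(d) {
    sqrt(diff(d$x)^2 + diff(d$y)^2)
  }))
  # grand mean step within 10% of the 415 m target
  expect_gt(mean(steps), 373)
  expect_lt(mean(steps), 457)
  # ellipse areas average near 2115 m^2 and a sizeable fraction exceed it
  expect_lt(abs(mean(tel$ellipse_area) - 2115) / 2115, 0.1)
  expect_gt(mean(tel$ellipse_area > 2115), 0.25)

  # determinism
  tel2 <- generate_telemetry(cfg, landscape, fawns)
  expect_identical(tel, tel2)
})

test_that("zero fawns yields an empty telemetry table with a warning", {
  cfg <- tiny_config()
  cfg$n_fawns <- 0L
  w <- tiny_world()
  fawns0 <- w$fawns[0, , drop = FALSE]
  expect_warning(tel <- generate_telemetry(cfg, w$landscape, fawns0),
                 "empty")
  expect_equal(nrow(tel), 0)
})

test_that("fates with beta = 0 and constant hazard are exponential", {
  h0 <- 0.01
  cfg <- sim_config(seed = 9, n_fawns = 500, baseline_hazard = h0,
                    frailty_sd_fawn = 0, frailty_sd_year = 0,
                    season_length = 100000L, birth_window = 0L,
                    true_cox_betas = c(resource_use = 0))
  covs <- data.frame(fawn_id = sprintf("F%03d", 1:500),
                     year = rep(1:3, length.out = 500),
                     birth_date = 0L, resource_use = rnorm(500))
  fates <- generate_fates(cfg, covs)
  expect_true(all(fates$event == 1))
  # closed-form exponential mean 1/h0, SE (1/h0)/sqrt(n)
  se <- (1 / h0) / sqrt(500)
  expect_lt(abs(mean(fates$stop_day) - 1 / h0), 2 * se)
})

test_that("zero hazard censors everyone at season end", {
  cfg <- sim_config(seed = 9, n_fawns = 50, baseline_hazard = 0,
                    true_cox_betas = c(resource_use = 0))
  covs <- data.frame(fawn_id = sprintf("F%02d", 1:50), year = 1,
                     birth_date = 5L, resource_use = 0)
  fates <- generate_fates(cfg, covs)
  expect_true(all(fates$event == 0))
  expect_true(all(fates$cause == "censored"))
  expect_true(all(fates$stop_day == cfg$season_length - 5))
})

test_that("a doubled hazard group recovers a fitted HR near 2", {
  n <- 1000
  cfg <- sim_config(seed = 13, n_fawns = n, baseline_hazard = 0.005,
                    frailty_sd_fawn = 0, frailty_sd_year = 0,
                    season_length = 109L, birth_window = 0L,
                    true_cox_betas = c(group = log(2)))
  covs <- data.frame(fawn_id = sprintf("F%04d", 1:n),
                     year = rep(1:3, length.out = n), birth_date = 0L,
                     group = rep(0:1, length.out = n))
  fates <- generate_fates(cfg, covs)
  records <- cbind(fates, group = covs$group)
  fit <- fit_cox(records, "group", random_effects = NULL)
  hr <- fit$coefficients$hazard_ratio
  expect_gt(hr, 1.8)
  expect_lt(hr, 2.2)
})

test_that("negative hazard parameters are rejected", {
  cfg <- tiny_config()
  cfg$baseline_hazard <- -0.1
  expect_error(generate_fates(cfg, data.frame(fawn_id = "a", year = 1,
                                              birth_date = 0)),
               "non-negative")
})

test_that("fate generator is deterministic and respects censoring bounds", {
  w <- tiny_world()
  covs <- data.frame(fawn_id = w$fawns$fawn_id, year = w$fawns$year,
                     birth_date = w$fawns$birth_date,
                     resource_use = rnorm(nrow(w$fawns)),
                     predation_risk = rnorm(nrow(w$fawns)),
                     birth_mass = rnorm(nrow(w$fawns)),
                     winter_severity = rnorm(nrow(w$fawns)))
  cfg <- w$config
  f1 <- generate_fates(cfg, covs)
  f2 <- generate_fates(cfg, covs)
  expect_identical(f1, f2)
  expect_true(all(f1$stop_day > 0))
  expect_true(all(f1$stop_day <= cfg$season_length - f1$birth_date + 1e-9))
  expect_true(all(f1$cause[f1$event == 0] == "censored"))
  expect_true(all(f1$cause[f1$event == 1] != "censored"))
})

test_that("weather table covers Jan-Mar daily with non-negative precipitation", {
  w <- tiny_world()
  expect_true(all(w$weather$snow_cm >= 0))
  expect_true(all(w$weather$wind_kph >= 0))
  expect_true(all(w$weather$rain_cm >= 0))
  days <- table(w$weather$year)
  expect_true(all(days == 90)) # non-leap synthetic years
})

test_that("fawn metadata respects capture-age bounds and mass back-projection", {
  w <- tiny_world()
  expect_true(all(w$fawns$age_at_capture >= 0 & w$fawns$age_at_capture <= 15))
  expect_equal(w$fawns$capture_mass,
               w$fawns$birth_mass_true + 0.2 * w$fawns$age_at_capture)
})
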