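# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small but complete synthetic world (fast: ~2 s)
tiny_config <- function(seed = 11) {
  sim_config(seed = seed, extent = c(2000, 2000), n_fawns = 40, n_years = 3)
}

tiny_world <- function() {
  fixture("tiny_world", function() {
    cfg <- tiny_config()
    landscape <- generate_landscape(cfg)
    weather <- generate_weather(cfg)
    fawns <- generate_fawns(cfg, weather)
    telemetry <- generate_telemetry(cfg, landscape, fawns)
    list(config = cfg, landscape = landscape, weather = weather,
         fawns = fawns, telemetry = telemetry)
  })
}

# a hand-built two-class landscape with a vertical class boundary at x = bx
split_landscape <- function(extent = 1000, res = 10, bx = 500) {
  nc <- extent / res
  m <- matrix(rep(ifelse((seq_len(nc) - 0.5) * res < bx, 1, 2), each = nc),
              nrow = nc, ncol = nc, byrow = FALSE)
  # columns left of bx are class 1: build by column index
  m <- matrix(0, nc, nc)
  for (j in seq_len(nc)) m[, j] <- ifelse((j - 0.5) * res < bx, 1, 2)
  uni <- function(v) fs_raster(matrix(v, nc, nc), cellsize = res)
  list(
    landcover = fs_raster(m, cellsize = res),
    roads = fs_roads(list(rbind(c(0, 0), c(extent, 0)))),
    predators = list(bobcat = uni(0.2), black_bear = uni(0.3),
                     coyote = uni(0.4), wolf = uni(0.1)),
    ndvi = uni(0.5),
    class_names = c("a", "b")
  )
}

# minimal cox_fit stand-in for surface tests
fake_cox_fit <- function(terms, betas, baseline, name = "fake") {
  structure(list(
    model_name = name, terms = terms, random_effects = NULL,
    coefficients = data.frame(term = terms, estimate = betas,
                              se = rep(0.1, length(terms)),
                              z = betas / 0.1, p = 0.5,
                              hazard_ratio = exp(betas)),
    frailty_var = numeric(0), loglik = NA_real_, n = 0L, n_events = 0L,
    df = 0, n_terms = length(terms), baseline = baseline,
    records_fingerprint = c(n = 0, sum_t = 0, sum_e = 0)
  ), class = "cox_fit")
}

# identity scaler over given columns
unit_scaler <- function(cols) {
  list(mean = setNames(rep(0, length(cols)), cols),
       sd = setNames(rep(1, length(cols)), cols))
}

expect_no_na <- function(x) expect_false(anyNA(x))
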