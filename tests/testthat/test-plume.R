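test_that("mean interval follows the centerline and cross-stream laws", {
  # lam = 0 collapses the centerline law to delta0
  pp <- plume_params(delta0 = 1, lam = 0)
  expect_equal(mean_interval(100, 0, pp), 1.0)
  # closed form: delta0 * exp(lam * x)
  pp <- plume_params(delta0 = 1, lam = 0.01)
  expect_equal(mean_interval(100, 0, pp), exp(1))
  # cross-stream law depends on |y| only
  pp <- plume_params()
  expect_equal(mean_interval(100, 5, pp), mean_interval(100, -5, pp))
  # domain: defined for x > 0 only
  expect_error(mean_interval(0, 0, pp), "x > 0")
  expect_error(mean_interval(-10, 2, pp), "x > 0")
})

test_that("mean concentration follows the centerline and Gaussian laws", {
  pp <- plume_params(c0 = 10, beta = 0)
  expect_equal(mean_concentration(50, 0, pp), 10)
  pp <- plume_params(c0 = 10, beta = 0.02)
  expect_equal(mean_concentration(50, 0, pp), 10 * exp(-1))
  # Gaussian tail vanishes far off-axis
  expect_lt(mean_concentration(50, 1e3, plume_params()), 1e-10)
  expect_error(mean_concentration(0, 0, pp), "x > 0")
})

test_that("plume statistics are monotone in distance from source and centerline", {
  pp <- plume_params()
  xs <- seq(50, 250, by = 10)
  expect_true(all(diff(mean_interval(xs, 0, pp)) > 0))
  expect_true(all(diff(mean_concentration(xs, 0, pp)) < 0))
  ys <- seq(0.5, 10, by = 0.5)
  for (x in c(50, 150, 250)) {
    expect_true(all(diff(mean_interval(x, ys, pp)) > 0))
    expect_true(all(diff(mean_concentration(x, ys, pp)) < 0))
  }
})

test_that("deterministic evaluations are bit-reproducible with noise_sd = 0", {
  pp <- plume_params()
  g <- expand.grid(x = c(50, 150, 250), y = c(0, 5, 10))
  expect_identical(mean_interval(g$x, g$y, pp), mean_interval(g$x, g$y, pp))
  expect_identical(mean_concentration(g$x, g$y, pp),
                   mean_concentration(g$x, g$y, pp))
})

test_that("concentration draws follow the site Gamma distribution", {
  pp <- plume_params()
  mu <- mean_concentration(150, 0, pp)
  sc <- concentration_scale(150, 0, pp)
  shape <- mu / sc
  set.seed(101)
  x <- sample_concentration(150, 0, pp, n = 1e5)
  # empirical mean within 3 standard errors of the model mean
  expect_lt(abs(mean(x) - mu), 3 * sqrt(shape) * sc / sqrt(1e5))
  # empirical variance close to shape * scale^2
  expect_lt(abs(var(x) - shape * sc^2) / (shape * sc^2), 0.1)
})

test_that("encounter gaps are exponential and memoryless", {
  pp <- plume_params()
  mu <- mean_interval(150, 0, pp)
  set.seed(7)
  times <- sample_encounter_times(150, 0, duration = 4000, params = pp)
  gaps <- diff(times)
  # distribution shape against the exponential with the model mean
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = 1 / mu))
  expect_gt(ks$p.value, 0.01)
  # memorylessness: residual gap beyond s is distributed as the full gap
  s <- mu / 2
  resid <- gaps[gaps > s] - s
  ks2 <- suppressWarnings(stats::ks.test(resid, gaps))
  expect_gt(ks2$p.value, 0.01)
  # renewal rate identity: expected count ~ duration / mean
  expect_lt(abs(length(times) - 4000 / mu) / (4000 / mu), 0.1)
  # negligible arrival probability over a short window
  set.seed(8)
  expect_length(sample_encounter_times(150, 0, duration = 10,
                                       params = plume_params(delta0 = 1e9)),
                0)
})

test_that("synthetic site series have whiff/blank structure at the renewal rate", {
  pp <- plume_params()
  set.seed(21)
  s <- generate_site_series(250, 0, duration = 300, params = pp)
  mu <- mean_interval(250, 0, pp)  # ~3 s, well above the whiff width
  n_up <- length(detect_upcrossings(s, pp$detect_threshold))
  expect_lt(abs(n_up - 300 / mu) / (300 / mu), 0.25)
  # baseline sits below the detection threshold between whiffs
  expect_lt(min(s$values), pp$detect_threshold)
  # seeded determinism
  set.seed(77); a <- generate_site_series(150, 5, params = pp)
  set.seed(77); b <- generate_site_series(150, 5, params = pp)
  expect_identical(a$values, b$values)
  # an effectively whiff-free plume stays below threshold everywhere
  set.seed(3)
  quiet <- generate_site_series(150, 0, duration = 5,
                                params = plume_params(delta0 = 1e9))
  expect_true(all(quiet$values < pp$detect_threshold))
})

test_that("whiff peaks always exceed the detection threshold", {
  pp <- plume_params()
  set.seed(12)
  for (site in list(c(50, 0), c(250, 0), c(150, 10))) {
    s <- generate_site_series(site[1], site[2], duration = 60, params = pp)
    if (length(s$encounter_times) > 0)
      expect_gte(max(s$values), pp$detect_threshold)
  }
})

test_that("model constants are recoverable from a measurement grid", {
  truth <- plume_params(delta0 = 0.2, lam = 0.01, g = 0.2, h = 0.01,
                        p = 2, q = -0.4, c0 = 12, beta = 0.01,
                        k = 12, b = -0.01, m = 0.6, d = 0.55)
  grid <- expand.grid(x = seq(40, 260, by = 20), y = c(0, 2.5, 5, 7.5, 10))
  grid$interval_mean <- mean_interval(grid$x, grid$y, truth)
  grid$conc_mean <- mean_concentration(grid$x, grid$y, truth)
  fit <- fit_plume_params(grid)
  for (f in c("delta0", "lam", "g", "h", "p", "q", "c0", "beta", "k", "b",
              "m", "d"))
    expect_equal(fit[[f]], truth[[f]], tolerance = 1e-6, label = f)
})

test_that("plume config round-trips and rejects unknown keys", {
  pp <- plume_params(delta0 = 0.3, lam = 0.02)
  path <- tempfile(fileext = ".yaml")
  write_plume_config(pp, path)
  back <- read_plume_config(path)
  expect_equal(unclass(back), unclass(pp))
  writeLines("delta0: 1\nbogus_key: 2", path)
  expect_error(read_plume_config(path), "bogus_key")
  expect_error(read_plume_config(tempfile()), "cannot read")
})

test_that("site series validate their contract and export to CSV", {
  expect_error(site_series(values = c(1)), "at least 2")
  expect_error(site_series(values = c(1, -2)), ">= 0")
  expect_error(site_series(values = c(1, 2), dt = 0), "dt")
  s <- site_series(x = 150, y = 0, values = c(0, 1, 2), dt = 0.5)
  path <- tempfile(fileext = ".csv")
  write_site_series_csv(s, path)
  df <- read.csv(path)
  expect_equal(df$t_seconds, c(0, 0.5, 1))
  expect_equal(df$concentration_pct, c(0, 1, 2))
})
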