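test_that("evoked-response sigmoid has the stated closed form", {
  p <- born_params(ibi_mean = 5, evoked_max = 1, evoked_mid = 2,
                   evoked_slope = 1)
  expect_equal(evoked_prob(2, p), 0.5)
  expect_equal(evoked_prob(4, p), 1 / (1 + exp(-2)))
  expect_equal(evoked_prob(1e6, p), 1)
  tau <- seq(0, 20, by = 0.1)
  expect_true(all(diff(evoked_prob(tau, p)) > 0))
})

test_that("spontaneous survival matches the IBI distribution", {
  p <- born_params(ibi_mean = 5, ibi_cv = 0.3)
  expect_equal(survival_prob(0, p), 1)
  # median IBI has survival one half
  sr <- plumetime:::.ibi_shape_rate(p)
  med <- qgamma(0.5, shape = sr$shape, rate = sr$rate)
  expect_equal(survival_prob(med, p), 0.5)
  # agrees with numerical integration of the density at tau = mean
  num <- integrate(function(u) dgamma(u, shape = sr$shape, rate = sr$rate),
                   5, Inf)$value
  expect_equal(survival_prob(5, p), num, tolerance = 1e-6)
  tau <- seq(0, 30, by = 0.1)
  expect_true(all(diff(survival_prob(tau, p)) <= 0))
  # lognormal alternative keeps the contract
  pl <- born_params(ibi_mean = 5, ibi_cv = 0.3, family = "lnorm")
  expect_equal(survival_prob(0, pl), 1)
  expect_true(all(diff(survival_prob(tau, pl)) <= 0))
})

test_that("the tuning curve is unimodal with an interior peak", {
  p <- born_params(ibi_mean = 5)
  tau <- seq(0, 40, by = 0.05)
  tc <- tuning_curve(tau, p)
  expect_lt(tc[1], 0.05)                   # refractory right after a burst
  expect_lt(tc[length(tc)], 1e-3)          # survival vanishes eventually
  peak <- which.max(tc)
  expect_gt(peak, 1)
  expect_lt(peak, length(tc))
  # increasing then decreasing around the peak
  expect_true(all(diff(tc[1:peak]) >= 0))
  expect_true(all(diff(tc[peak:length(tc)]) <= 0))
})

test_that("population construction spans the period range reproducibly", {
  set.seed(1)
  pop <- make_population(210, period_range = c(0.2, 20))
  expect_length(pop, 210)
  means <- vapply(pop, `[[`, numeric(1), "ibi_mean")
  expect_true(all(means >= 0.2 & means <= 20))
  set.seed(1)
  pop2 <- make_population(210, period_range = c(0.2, 20))
  expect_identical(pop, pop2)
  expect_length(make_population(1), 1)
})

test_that("spontaneous bursting reproduces the configured IBI statistics", {
  p <- born_params(ibi_mean = 2, ibi_cv = 0.3)
  set.seed(2)
  b <- simulate_born(p, numeric(0), duration = 4000)
  ibis <- diff(b)
  expect_lt(abs(mean(ibis) - 2) / 2, 0.05)
  expect_lt(abs(sd(ibis) / mean(ibis) - 0.3) / 0.3, 0.15)
  # near-periodic limit at vanishing cv
  set.seed(3)
  b0 <- simulate_born(born_params(ibi_mean = 2, ibi_cv = 0.01), numeric(0),
                      duration = 100)
  expect_lt(sd(diff(b0)), 0.1)
  expect_true(all(diff(b) > 0))
  expect_error(simulate_born(p, c(3, 1), duration = 10), "sorted")
})

test_that("response probability is phase-dependent as in the renewal model", {
  p <- born_params(ibi_mean = 4, ibi_cv = 0.25)
  # odors arriving right after a burst are ignored
  expect_lt(evoked_prob(0.05, p), 0.01)
  # entrainment: odors at the tuning-curve peak period evoke more responses
  # than odors arriving ten times faster
  tau_grid <- seq(0.05, 20, by = 0.05)
  t_peak <- tau_grid[which.max(tuning_curve(tau_grid, p))]
  freq_at <- function(period) {
    odors <- seq(period, 60, by = period)
    hits <- replicate(60, {
      b <- simulate_born(p, odors, duration = 60)
      mean(attr(b, "responded"))
    })
    mean(hits)
  }
  set.seed(5)
  expect_gt(freq_at(t_peak), freq_at(t_peak / 10))
})

test_that("population rasters match single-neuron statistics", {
  set.seed(6)
  pop <- make_population(20, period_range = c(1, 5))
  raster <- simulate_population(pop, odor_times = c(10, 20), duration = 30)
  expect_length(raster$bursts, 20)
  expect_true(all(vapply(raster$bursts,
                         function(b) all(diff(b) > 0), logical(1))))
  # per-neuron spontaneous rate agrees with the neuron's own simulation
  set.seed(7)
  long <- simulate_population(pop[1:3], numeric(0), duration = 600)
  for (i in 1:3) {
    got <- mean(diff(long$bursts[[i]]))
    expect_lt(abs(got - pop[[i]]$ibi_mean) / pop[[i]]$ibi_mean, 0.2)
  }
  # seeded determinism
  set.seed(8); r1 <- simulate_population(pop, c(5), 10)
  set.seed(8); r2 <- simulate_population(pop, c(5), 10)
  expect_identical(r1$bursts, r2$bursts)
  # empty population gives an empty raster
  empty <- simulate_population(structure(list(), class = c("born_population",
                                                           "list")),
                               numeric(0), 10)
  expect_length(empty$bursts, 0)
})

test_that("population state reads out per-neuron elapsed times", {
  raster <- structure(list(bursts = list(c(1, 4), c(2), numeric(0)),
                           odor_times = numeric(0), duration = 10,
                           pop = make_population(3)),
                      class = "burst_raster")
  st <- state_at(raster, 5)
  expect_equal(st$tau[1], 1)       # last burst at 4
  expect_equal(st$tau[2], 3)
  expect_true(is.na(st$tau[3]))    # never burst: flagged invalid
  expect_equal(st$valid, c(TRUE, TRUE, FALSE))
  st4 <- state_at(raster, 4)
  expect_equal(st4$tau[1], 0)      # queried exactly at a burst
  expect_error(state_at(raster, 11), "outside")
  expect_error(state_at(raster, -1), "outside")
})

test_that("maximum-likelihood decoding finds the encoded interval", {
  # single neuron with a dominant response kernel: the likelihood peaks at
  # the grid point matching its phase
  p <- born_params(ibi_mean = 10, ibi_cv = 0.3)
  st <- structure(list(neurons = list(p), tau = 7.5, valid = TRUE,
                       t_now = 100), class = "population_state")
  dec <- decode_elapsed_time(st, t_grid = c(5, 7.5, 10))
  expect_equal(dec$t_hat, 7.5)
  # brute-force check of the likelihood values themselves
  w <- plumetime:::.mean_evoked(p) * survival_prob(c(5, 7.5, 10), p)
  g <- survival_prob(7.5, p) / p$ibi_mean
  manual <- log(w * dnorm(7.5 - c(5, 7.5, 10), sd = 0.25) + (1 - w) * g)
  expect_equal(dec$loglik, manual)
  # responders that just burst decode to zero elapsed time
  pop <- replicate(5, born_params(ibi_mean = 5), simplify = FALSE)
  st0 <- structure(list(neurons = pop, tau = rep(0, 5),
                        valid = rep(TRUE, 5), t_now = 1),
                   class = "population_state")
  expect_equal(decode_elapsed_time(st0, seq(0, 10, 0.5))$t_hat, 0)
  # no valid neurons is an error
  stbad <- structure(list(neurons = pop, tau = rep(NA_real_, 5),
                          valid = rep(FALSE, 5), t_now = 1),
                     class = "population_state")
  expect_error(decode_elapsed_time(stbad), "no valid neurons")
})

test_that("winner-take-all picks the modal phase", {
  pop <- replicate(6, born_params(ibi_mean = 5), simplify = FALSE)
  st <- structure(list(neurons = pop, tau = rep(3.2, 6),
                       valid = rep(TRUE, 6), t_now = 10),
                  class = "population_state")
  expect_equal(winner_take_all(st), 3.2)
  st2 <- structure(list(neurons = pop, tau = c(1.1, 1.2, 1.3, 8.1, 8.2, 1.15),
                        valid = rep(TRUE, 6), t_now = 10),
                   class = "population_state")
  expect_lt(winner_take_all(st2, bin_width = 1), 2)  # taller mode near 1
  # agreement with the ML decoder on a strongly entrained population (long
  # intrinsic periods, so most neurons respond to the stimulus and hold
  # their phase until readout)
  set.seed(9)
  pop <- make_population(210, period_range = c(10, 40))
  raster <- simulate_population(pop, odor_times = c(30, 38), duration = 39)
  st3 <- state_at(raster, 38 - 1e-9)
  ml <- decode_elapsed_time(st3)$t_hat
  wta <- winner_take_all(st3, bin_width = 0.5)
  expect_lt(abs(ml - wta), 1)
})

test_that("raster and decoder tables export to CSV", {
  set.seed(10)
  pop <- make_population(5)
  raster <- simulate_population(pop, c(2), 5)
  path <- tempfile(fileext = ".csv")
  write_raster_csv(raster, path)
  df <- read.csv(path)
  expect_named(df, c("neuron_id", "burst_time_s"))
  expect_equal(nrow(df), sum(lengths(raster$bursts)))
  dec <- decode_elapsed_time(state_at(raster, 4), seq(0, 5, 0.5))
  path2 <- tempfile(fileext = ".csv")
  write_decode_csv(dec, path2)
  df2 <- read.csv(path2)
  expect_equal(sum(df2$is_argmax), 1)
  expect_equal(df2$t_grid_s[df2$is_argmax], dec$t_hat)
})
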