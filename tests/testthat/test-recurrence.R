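test_that("delay embedding has the right geometry", {
  s <- site_series(values = 1:10, dt = 1)
  # dimension 1 reproduces the raw series
  tr <- delay_embed(s, embed_config(dim = 1, delay = 1))
  expect_equal(as.numeric(tr$points), 1:10)
  # N = length - (dim - 1) * delay
  tr <- delay_embed(s, embed_config(dim = 3, delay = 2))
  expect_equal(nrow(tr$points), 6)
  expect_equal(tr$points[1, ], c(1, 3, 5))
  expect_equal(tr$points[6, ], c(6, 8, 10))
  expect_error(delay_embed(s, embed_config(dim = 6, delay = 2)), "too short")
})

test_that("automatic delay selection lands on a sensible lag", {
  t <- seq(0, 40, by = 0.1)
  s <- site_series(values = sin(2 * pi * t / 4) + 2, dt = 0.1)
  d <- choose_delay(s)
  expect_gte(d, 1)
  expect_lte(d, 40)  # at most one period of the oscillation
})

test_that("recurrence matrix matches the brute-force oracle exactly", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(20:200, 1)
    s <- site_series(values = abs(rnorm(n, 2, 1)), dt = 1)
    dim <- sample(1:4, 1)
    delay <- sample(1:3, 1)
    r <- runif(1, 0.2, 2)
    tr <- delay_embed(s, embed_config(dim = dim, delay = delay))
    R <- recurrence_matrix(tr, r)
    expect_identical(R, naive_recurrence_matrix(tr$points, r))
  }
  # forced example: 1-D points {0, 1, 1.4}, r = 0.5
  R <- recurrence_matrix(matrix(c(0, 1, 1.4), ncol = 1), r = 0.5)
  expect_equal(unname(R),
               matrix(c(TRUE, FALSE, FALSE,
                        FALSE, TRUE, TRUE,
                        FALSE, TRUE, TRUE), 3, 3))
})

test_that("recurrence matrix is symmetric with a unit diagonal", {
  set.seed(9)
  tr <- delay_embed(site_series(values = runif(100), dt = 1),
                    embed_config(dim = 3, delay = 1))
  R <- recurrence_matrix(tr, 0.4)
  expect_true(all(diag(R)))
  expect_identical(R, t(R))
})

test_that("neighbor search honors the radius and grows with it", {
  set.seed(10)
  tr <- delay_embed(site_series(values = runif(200), dt = 1),
                    embed_config(dim = 2, delay = 1))
  x0 <- tr$points[17, ]
  expect_true(17 %in% neighbor_times(tr, x0, r = 0.1))  # zero distance
  expect_length(neighbor_times(tr, x0 + 100, r = 0.1), 0)
  sizes <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
                  function(r) length(neighbor_times(tr, x0, r)), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("recurrence times reproduce the hand-enumerated example", {
  s <- site_series(values = c(0, 1, 1, 1, 0, 0, 1, 1, 0, 0, 0, 1), dt = 1)
  tr <- delay_embed(s, embed_config(dim = 1, delay = 1))
  rt <- recurrence_times(tr, x0 = 1, r = 0.5)
  expect_equal(rt$s1, c(2, 3, 4, 7, 8, 12))
  expect_equal(rt$t1_intervals, c(1, 1, 3, 1, 4))
  expect_equal(rt$t1_mean, 2.0)
  expect_equal(rt$s2, c(2, 7, 12))
  expect_equal(rt$t2_intervals, c(5, 5))
  expect_equal(rt$t2_mean, 5.0)
})

test_that("recurrence times match the brute-force oracle on random series", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(30:200, 1)
    s <- abs(rnorm(n, 2, 1))
    dim <- sample(1:3, 1)
    tr <- delay_embed(site_series(values = s, dt = 0.5),
                      embed_config(dim = dim, delay = 1))
    x0 <- tr$points[sample(nrow(tr$points), 1), ]
    r <- runif(1, 0.3, 1.5)
    got <- recurrence_times(tr, x0, r)
    want <- naive_recurrence_times(tr$points, x0, r, dt = 0.5)
    expect_identical(got$s1, want$s1)
    expect_identical(got$s2, want$s2)
    expect_equal(got$t1_intervals, want$t1)
    expect_equal(got$t2_intervals, want$t2)
    expect_equal(got$t1_mean, want$t1_mean)
    expect_equal(got$t2_mean, want$t2_mean)
  }
})

test_that("periodic revisits give equal first- and second-type times", {
  # one isolated neighborhood visit per cycle of period 10 samples
  s <- rep(c(5, rep(0, 9)), 8)
  rt <- recurrence_times(matrix(s, ncol = 1), x0 = 5, r = 0.5, dt = 1)
  expect_equal(rt$t1_mean, 10)
  expect_equal(rt$t2_mean, 10)
})

test_that("a single sojourn run yields dt-spaced T1 and undefined T2", {
  rt <- recurrence_times(matrix(rep(1, 6), ncol = 1), x0 = 1, r = 0.5, dt = 2)
  expect_true(all(rt$t1_intervals == 2))
  expect_equal(rt$n_returning, 1)
  expect_true(is.na(rt$t2_mean))
})

test_that("second-type times never fall below first-type times", {
  set.seed(12)
  for (rep in 1:100) {
    s <- abs(rnorm(sample(50:150, 1), 2, 1))
    tr <- delay_embed(site_series(values = s, dt = 1),
                      embed_config(dim = 1, delay = 1))
    x0 <- tr$points[sample(nrow(tr$points), 1), ]
    rt <- recurrence_times(tr, x0, r = runif(1, 0.3, 1))
    if (!is.na(rt$t1_mean) && !is.na(rt$t2_mean))
      expect_gte(rt$t2_mean, rt$t1_mean)
  }
})

test_that("sojourn clustering with a refractory window merges close visits", {
  # visits at steps 1,2 then 10,12 then 30; window of 3 s at dt = 1
  pts <- matrix(0, 30, 1)
  pts[c(1, 2, 10, 12, 30), 1] <- 1
  rt <- recurrence_times(pts, x0 = 1, r = 0.5, dt = 1, min_separation = 3)
  expect_equal(rt$s2, c(1, 10, 30))
  # default keeps the consecutive-sample rule: 12 is its own return
  rt0 <- recurrence_times(pts, x0 = 1, r = 0.5, dt = 1)
  expect_equal(rt0$s2, c(1, 10, 12, 30))
})

test_that("upcrossing detection scans the threshold correctly", {
  expect_equal(detect_upcrossings(c(0, 3, 3, 0, 3), 2.55, dt = 1), c(1, 4))
  expect_length(detect_upcrossings(rep(1, 10), 2.55, dt = 1), 0)
  # a series starting above threshold needs a below-to-above transition
  expect_equal(detect_upcrossings(c(5, 5, 0, 5), 2.55, dt = 1), 3)
})

test_that("site profiles aggregate replicates stably", {
  pp <- plume_params()
  cfg <- embed_config(dim = 1, delay = 1, r = 0.33, reference = 2.55)
  set.seed(30)
  reps <- lapply(1:4, function(i)
    generate_site_series(100, 0, duration = 30, params = pp))
  tab <- site_profile(reps, cfg)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_rep, 4)
  # replicate order is irrelevant
  tab2 <- site_profile(rev(reps), cfg)
  expect_equal(tab$t1_mean_s, tab2$t1_mean_s)
  expect_equal(tab$t2_mean_s, tab2$t2_mean_s)
  # a single replicate reports sd = 0
  tab1 <- site_profile(reps[1], cfg)
  expect_equal(tab1$t1_sd_s, 0)
  # raw-series and embedded profiles rank a sparse vs a dense site alike
  set.seed(31)
  dense <- lapply(1:3, function(i)
    generate_site_series(50, 0, duration = 60, params = pp))
  sparse <- lapply(1:3, function(i)
    generate_site_series(250, 0, duration = 60, params = pp))
  for (d in c(1, 3)) {
    cfgd <- embed_config(dim = d, delay = 1, r = 0.33, reference = 2.55)
    tabd <- site_profile(c(dense, sparse), cfgd, pool = "intervals")
    expect_lt(tabd$t1_mean_s[tabd$site_x_cm == 50],
              tabd$t1_mean_s[tabd$site_x_cm == 250])
  }
})
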