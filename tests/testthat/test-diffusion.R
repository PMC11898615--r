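dt <- 0.013

test_that("jump distances follow the geometry of the tracks", {
  still <- data.frame(track_id = 1, frame = 0:4, x_um = 1, y_um = 1)
  jd <- compute_jump_distances(still, dt = dt)
  expect_equal(jd$r2, rep(0, 4))

  tri <- data.frame(track_id = 1, frame = 0:1,
                    x_um = c(0, 0.3), y_um = c(0, 0.4))
  expect_equal(compute_jump_distances(tri, dt = dt)$r2, 0.25)

  five <- data.frame(track_id = 1, frame = 0:4,
                     x_um = cumsum(rep(0.1, 5)), y_um = 0)
  expect_length(compute_jump_distances(five, dt = dt)$r2, 4)
  # lag larger than track length contributes nothing
  expect_length(compute_jump_distances(five, dt = dt, lag = 5)$r2, 0)
})

test_that("k = 1 CDF fit agrees with the moment estimator on clean data", {
  cells <- big_cells(seed = 51)
  mix <- sim_mixture_config(k = 1, D = 0.1, f = 1, loc_sd = 0,
                            n_tracks = 2500, seed = 52)
  sim <- simulate_tracks(cells, mix)
  jd <- compute_jump_distances(sim$tracks, dt = dt)
  fit <- fit_sqd_mixture(jd, k = 1)
  moment <- mean(jd$r2) / (4 * dt)
  expect_lt(abs(fit$D - moment) / moment, 0.02)
  expect_equal(fit$f, 1)
})

test_that("fractions of any successful fit sum to one and D are ascending", {
  set.seed(53)
  mu <- 4 * c(0.02, 0.3) * dt
  r2 <- rexp(4000, 1 / mu[sample(1:2, 4000, TRUE)])
  for (m in c("cdf", "mle")) {
    fit <- fit_sqd_mixture(r2, k = 2, dt = dt, method = m)
    expect_equal(sum(fit$f), 1, tolerance = 1e-6)
    expect_false(is.unsorted(fit$D))
    expect_true(all(fit$D >= 0) && all(fit$f >= 0))
  }
})

test_that("three-component CDF fit recovers a planted mixture", {
  # the empirical-CDF estimator is noisy at this separation (D ratios 3 and
  # 8), so the recovery claim is checked as the median error over 5 seeds
  n <- 30000
  D_true <- c(0.017, 0.0509, 0.394)
  f_true <- c(0.33, 0.33, 0.34)
  errs <- sapply(1:5, function(s) {
    set.seed(540 + s)
    pop <- sample(1:3, n, TRUE, prob = f_true)
    r2 <- rexp(n, 1 / (4 * D_true[pop] * dt))
    fit <- fit_sqd_mixture(r2, k = 3, dt = dt)
    c(max(abs(fit$D - D_true) / D_true), max(abs(fit$f - f_true)))
  })
  expect_lte(median(errs[1, ]), 0.15)
  expect_lte(median(errs[2, ]), 0.05)
})

test_that("mixture fit is invariant to shuffling the jump order", {
  set.seed(55)
  r2 <- rexp(3000, 1 / (4 * 0.05 * dt))
  f1 <- fit_sqd_mixture(r2, k = 1, dt = dt)
  f2 <- fit_sqd_mixture(sample(r2), k = 1, dt = dt)
  expect_equal(f1$D, f2$D, tolerance = 1e-10)
})

test_that("error-corrected model removes the localization-error offset", {
  set.seed(56)
  sigma <- 0.03
  D_true <- 0.05
  n <- 20000
  # apparent squared displacements: 4 D dt + 4 sigma^2 exponential scale
  r2 <- rexp(n, 1 / (4 * D_true * dt + 4 * sigma^2))
  fit_plain <- fit_sqd_mixture(r2, k = 1, dt = dt)
  fit_corr <- fit_sqd_mixture(r2, k = 1, dt = dt, sigma = sigma)
  expect_gt(fit_plain$D, D_true * 1.3)  # apparent D inflated
  expect_lt(abs(fit_corr$D - D_true) / D_true, 0.05)
})

test_that("mixture order selection finds the planted k", {
  set.seed(57)
  one <- rexp(20000, 1 / (4 * 0.1 * dt))
  expect_equal(select_mixture_order(one, k_max = 3, dt = dt)$k, 1)

  D_true <- c(0.017, 0.0509 * 2, 0.394 * 3)  # ratios >= 5
  pop <- sample(1:3, 30000, TRUE, prob = c(1, 1, 1) / 3)
  three <- rexp(30000, 1 / (4 * D_true[pop] * dt))
  expect_equal(select_mixture_order(three, k_max = 3, dt = dt)$k, 3)

  expect_equal(select_mixture_order(one, k_max = 1, dt = dt)$k, 1)
})

test_that("insufficient data and bad orders are rejected", {
  expect_error(fit_sqd_mixture(rexp(40), k = 1, dt = dt), "at least")
  expect_error(fit_sqd_mixture(rexp(1000), k = 4, dt = dt), "k must be")
})

test_that("MSD of ballistic motion is exactly quadratic", {
  v <- 1  # um/s
  trk <- data.frame(track_id = 1, frame = 0:19,
                    x_um = v * (0:19) * dt, y_um = 0)
  msd <- compute_msd(trk, dt = dt, max_lag = 5)
  expect_equal(msd$msd, (v * msd$lag_s)^2, tolerance = 1e-12)
})

test_that("MSD fit recovers D from simulated diffusion", {
  cells <- big_cells(seed = 58)
  mix <- sim_mixture_config(k = 1, D = 0.05, f = 1, loc_sd = 0,
                            n_tracks = 5000, seed = 59)
  sim <- simulate_tracks(cells, mix)
  msd <- compute_msd(sim$tracks, dt = dt, max_lag = 4)
  expect_lt(abs(msd$D - 0.05) / 0.05, 0.10)
})

test_that("short tracks limit the available lags", {
  trk <- data.frame(track_id = 1, frame = 0:1, x_um = c(0, 0.1), y_um = 0)
  msd <- compute_msd(trk, dt = dt, max_lag = 3)
  expect_length(msd$lag_s, 1)
  expect_equal(msd$lag_s, dt)
})

test_that("D recovery bias shrinks as the jump count grows", {
  # median absolute error of the k=1 fit over 20 seeds at three sizes
  sizes <- c(1000, 10000, 100000)
  err <- sapply(sizes, function(n) {
    median(sapply(1:20, function(s) {
      set.seed(s * 1000 + n)
      r2 <- rexp(n, 1 / (4 * 0.05 * dt))
      abs(fit_sqd_mixture(r2, k = 1, dt = dt)$D - 0.05)
    }))
  })
  expect_true(all(diff(err) < 0))
})
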