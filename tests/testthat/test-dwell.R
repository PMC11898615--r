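dt <- 0.013

test_that("dwell events follow the anchored-run definition", {
  still <- data.frame(track_id = 1, frame = 0:9, x_um = 0, y_um = 0)
  ev <- extract_dwell_events(still, dt = dt)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 9 * dt)

  # fast directed motion: every consecutive pair exceeds the radius
  fast <- data.frame(track_id = 1, frame = 0:9,
                     x_um = 0.2 * (0:9), y_um = 0)
  expect_equal(nrow(extract_dwell_events(fast, dt = dt, r_dwell = 0.1)), 0)

  # a dwell, an excursion, then another dwell
  x <- c(0, 0.01, 0.02, 0.5, 1.0, 1.0, 1.01)
  trk <- data.frame(track_id = 1, frame = 0:6, x_um = x, y_um = 0)
  ev2 <- extract_dwell_events(trk, dt = dt, r_dwell = 0.1)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$n_frames, c(3, 3))
})

test_that("confined populations dwell longer than fast ones", {
  cells <- std_cells(seed = 61, n = 20)
  mix <- sim_mixture_config(k = 2, D = c(0.017, 0.394), f = c(0.5, 0.5),
                            loc_sd = 0, p_survive = 0.9, n_tracks = 800,
                            seed = 62)
  sim <- simulate_tracks(cells, mix)
  ev <- extract_dwell_events(sim$tracks, dt = dt)
  pop <- sim$truth$population[ev$track_id]
  expect_gt(mean(ev$duration_s[pop == 1]), mean(ev$duration_s[pop == 2]))
})

test_that("order-1 dwell fit equals the analytic truncated-exponential MLE", {
  set.seed(63)
  t_min <- 4 * dt
  d <- t_min + rexp(500, 1 / 0.27)
  fit <- fit_dwell_times(d, order = 1, t_min = t_min)
  expect_equal(fit$tau, mean(d) - t_min, tolerance = 1e-12)
})

test_that("order-2 dwell fit recovers a planted mixture", {
  # the two-exponential likelihood is flat at this tau ratio (~2.4), so the
  # recovery claim is checked as the median error over 5 seeds
  n <- 5000
  tau_true <- c(0.14, 0.33)
  errs <- sapply(1:5, function(s) {
    set.seed(640 + s)
    comp <- sample(1:2, n, TRUE)
    d <- rexp(n, 1 / tau_true[comp])
    fit <- fit_dwell_times(d, order = 2, t_min = 0)
    expect_equal(sum(fit$percent), 100, tolerance = 0.5)
    expect_lt(fit$tau[1], fit$tau[2])
    c(max(abs(fit$tau - tau_true) / tau_true),
      max(abs(fit$percent - c(50, 50))))
  })
  expect_lte(median(errs[1, ]), 0.2)
  expect_lte(median(errs[2, ]), 10)
})

test_that("degenerate durations fall back to order 1 with a warning", {
  d <- rep(0.1, 30)
  expect_warning(fit <- fit_dwell_times(d, order = 2), "degenerate")
  expect_equal(fit$order, 1L)
})

test_that("the dwell table mirrors the one- and two-component fits", {
  set.seed(65)
  lst <- list(a = rexp(300, 1 / 0.2), b = rexp(300, 1 / 0.3))
  tab <- dwell_time_table(lst)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$tau_s, vapply(lst, mean, numeric(1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(tab$tau1_s < tab$tau2_s))
  expect_equal(tab$tau1_pct + tab$tau2_pct, c(100, 100), tolerance = 0.5)
})
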