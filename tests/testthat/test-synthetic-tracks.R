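test_that("zero diffusion and zero noise give frozen tracks", {
  cells <- std_cells(seed = 1, n = 5)
  mix <- sim_mixture_config(k = 1, D = 0, f = 1, loc_sd = 0,
                            n_tracks = 50, seed = 2)
  sim <- simulate_tracks(cells, mix)
  for (tid in unique(sim$tracks$track_id)) {
    tr <- sim$tracks[sim$tracks$track_id == tid, ]
    expect_equal(diff(range(tr$x_um)), 0)
    expect_equal(diff(range(tr$y_um)), 0)
  }
})

test_that("mean squared step matches 4 D dt in an unconfined arena", {
  cells <- big_cells(seed = 3)
  mix <- sim_mixture_config(k = 1, D = 0.1, f = 1, loc_sd = 0,
                            p_survive = 0.85, n_tracks = 5000, seed = 4)
  sim <- simulate_tracks(cells, mix)
  jd <- compute_jump_distances(sim$tracks, dt = mix$dt)
  se <- stats::sd(jd$r2) / sqrt(length(jd$r2))
  expect_lt(abs(mean(jd$r2) - 4 * 0.1 * mix$dt), 3 * se)
})

test_that("pure localization noise gives MSD of 4 sigma^2", {
  cells <- std_cells(seed = 5, n = 10)
  mix <- sim_mixture_config(k = 1, D = 0, f = 1, loc_sd = 0.03,
                            n_tracks = 3000, seed = 6)
  sim <- simulate_tracks(cells, mix)
  jd <- compute_jump_distances(sim$tracks, dt = mix$dt)
  se <- stats::sd(jd$r2) / sqrt(length(jd$r2))
  expect_lt(abs(mean(jd$r2) - 4 * 0.03^2), 3 * se)
})

test_that("true positions never leave their cell", {
  cells <- std_cells(seed = 7, n = 20)
  mix <- sim_mixture_config(n_tracks = 500, seed = 8)
  sim <- simulate_tracks(cells, mix)
  L <- vapply(cells, `[[`, numeric(1), "length")[sim$tracks$cell_id]
  w <- vapply(cells, `[[`, numeric(1), "width")[sim$tracks$cell_id]
  expect_true(all(sc_contains(sim$tracks$true_x_um, sim$tracks$true_y_um,
                              L, w)))
})

test_that("population label frequencies follow the mixture fractions", {
  pass <- 0L
  for (s in 1:20) {
    cells <- std_cells(seed = 100 + s, n = 10)
    mix <- sim_mixture_config(k = 3, f = c(0.2, 0.3, 0.5),
                              D = c(0.017, 0.0509, 0.394),
                              n_tracks = 5000, seed = 200 + s)
    sim <- simulate_tracks(cells, mix)
    obs <- tabulate(sim$truth$population, 3)
    p <- stats::chisq.test(obs, p = mix$f)$p.value
    if (p >= 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 19L)
})

test_that("identical seeds reproduce tracks bit-identically, different differ", {
  cells <- std_cells(seed = 9, n = 5)
  mix <- sim_mixture_config(n_tracks = 100, seed = 10)
  s1 <- simulate_tracks(cells, mix)
  s2 <- simulate_tracks(cells, mix)
  expect_identical(s1$tracks, s2$tracks)
  mix2 <- sim_mixture_config(n_tracks = 100, seed = 11)
  s3 <- simulate_tracks(cells, mix2)
  expect_false(identical(s1$tracks, s3$tracks))
})

test_that("mixture config validates its invariants", {
  expect_error(sim_mixture_config(k = 4, D = rep(0.1, 4), f = rep(0.25, 4)),
               "k must be")
  expect_error(sim_mixture_config(k = 2, D = c(0.1, 0.2), f = c(0.6, 0.5)),
               "sum to 1")
  expect_error(sim_mixture_config(k = 1, D = -0.1, f = 1), "D must be")
  expect_error(sim_mixture_config(p_survive = 1), "p_survive")
})

test_that("septal bias places confined molecules at the septum plane", {
  cells <- simulate_cell_population(
    sim_cell_config(n_cells = 10, septum_prob = 1, seed = 12))
  mix <- sim_mixture_config(k = 1, D = 0, f = 1, loc_sd = 0,
                            septal_bias = 1, n_tracks = 300, seed = 13)
  sim <- simulate_tracks(cells, mix)
  first <- sim$tracks[!duplicated(sim$tracks$track_id), ]
  # septum plane is x = 0 in every (origin-centered) cell
  expect_true(all(abs(first$x_um) < 0.15))
})
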