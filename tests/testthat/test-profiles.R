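test_that("cell length is measured between the outermost membrane peaks", {
  p <- simulate_profiles(2.0, n_septa = 0, n_nucleoids = 0, noise_sd = 0)
  expect_equal(measure_cell_length(p), 2.0, tolerance = 0.01)

  # single-peak profile cannot be measured
  lone <- structure(list(position = seq(-1, 1, 0.0645),
                         membrane = exp(-seq(-1, 1, 0.0645)^2 / 0.01),
                         phase = NULL, dna = NULL),
                    class = "cell_profile")
  lone$phase <- lone$dna <- rep(0, length(lone$position))
  expect_error(measure_cell_length(lone), "fewer than 2")
})

test_that("length measurement is invariant to mirroring the profile", {
  p <- simulate_profiles(2.6, n_septa = 1, n_nucleoids = 2, noise_sd = 8,
                         seed = 81)
  rev_p <- p
  rev_p$membrane <- rev(p$membrane)
  rev_p$dna <- rev(p$dna)
  rev_p$phase <- rev(p$phase)
  expect_equal(measure_cell_length(p), measure_cell_length(rev_p),
               tolerance = 1e-9)
})

test_that("septa are counted inside the polar exclusion zone", {
  p1 <- simulate_profiles(3.0, n_septa = 1, n_nucleoids = 1, noise_sd = 0)
  expect_equal(count_septa(p1), 1L)
  p0 <- simulate_profiles(3.0, n_septa = 0, n_nucleoids = 1, noise_sd = 0)
  expect_equal(count_septa(p0), 0L)
})

test_that("nucleoid counting uses the trough-separation rule", {
  p0 <- simulate_profiles(3.0, n_septa = 0, n_nucleoids = 0, noise_sd = 0)
  expect_equal(count_nucleoids(p0), 0L)
  p2 <- simulate_profiles(3.0, n_septa = 0, n_nucleoids = 2, noise_sd = 0)
  expect_equal(count_nucleoids(p2), 2L)
  # two overlapping blobs with a shallow trough merge into one call
  pos <- seq(-1.5, 1.5, 0.0645)
  y <- exp(-(pos - 0.1)^2 / (2 * 0.15^2)) + exp(-(pos + 0.1)^2 / (2 * 0.15^2))
  prof <- structure(list(position = pos, phase = rep(0, length(pos)),
                         membrane = rep(0, length(pos)), dna = 100 * y),
                    class = "cell_profile")
  expect_equal(count_nucleoids(prof), 1L)
})

test_that("morphometrics hold up at realistic noise", {
  set.seed(82)
  n <- 150
  # draw all configurations up front (simulate_profiles reseeds the RNG)
  Ls <- runif(n, 2.2, 3.6)
  nss <- sample(0:2, n, TRUE)
  nns <- sample(1:3, n, TRUE)
  ok_len <- ok_sep <- ok_nuc <- 0L; n_ok <- 0L
  for (i in seq_len(n)) {
    p <- tryCatch(simulate_profiles(Ls[i], n_septa = nss[i],
                                    n_nucleoids = nns[i], noise_sd = 10,
                                    seed = 8200 + i),
                  error = function(e) NULL)  # geometrically infeasible combo
    if (is.null(p)) next
    n_ok <- n_ok + 1L
    len <- tryCatch(measure_cell_length(p), error = function(e) NA)
    if (!is.na(len) && abs(len - Ls[i]) <= 2 * 0.0645) ok_len <- ok_len + 1L
    if (!is.na(len) && count_septa(p) == nss[i]) ok_sep <- ok_sep + 1L
    if (count_nucleoids(p) == nns[i]) ok_nuc <- ok_nuc + 1L
  }
  expect_gte(n_ok, 100)
  expect_gte(ok_len / n_ok, 0.95)
  expect_gte(ok_sep / n_ok, 0.95)
  expect_gte(ok_nuc / n_ok, 0.90)
})

test_that("septal localization fraction counts threshold crossings", {
  expect_equal(septal_localization_fraction(rep(100, 10)), 0)
  expect_equal(septal_localization_fraction(rep(2000, 10)), 1)
  # 20-frame cycle, monotone trace crossing at frame 16
  trace <- seq(100, 2000, length.out = 20)
  expect_equal(septal_localization_fraction(trace, threshold = trace[16]),
               0.25)
  expect_error(septal_localization_fraction(rep(1, 5), cycle_start = 3,
                                            cycle_end = 2), "cycle")
})

test_that("planted earlier septal arrival is detected across traces", {
  set.seed(83)
  n_tr <- 45
  make_trace <- function(arrive_at) {
    tt <- 1:20
    1800 * plogis((tt - arrive_at) * 2) + rnorm(20, 0, 30) + 100
  }
  fr_a <- sapply(1:n_tr, function(i) septal_localization_fraction(
    make_trace(arrive_at = rnorm(1, 15, 1))))
  fr_b <- sapply(1:n_tr, function(i) septal_localization_fraction(
    make_trace(arrive_at = rnorm(1, 10, 1))))
  wt <- wilcoxon_rank_sum(fr_b, fr_a)
  expect_lt(wt$p_value, 0.01)
  expect_gt(mean(fr_b), mean(fr_a))
})
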