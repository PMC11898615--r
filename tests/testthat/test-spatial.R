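make_cell <- function(length = 3, width = 1, center = c(0, 0), id = 1) {
  cl <- list(cell_id = id,
             vertices = spherocylinder_polygon(length, width, center),
             poles = rbind(c(-length / 2, 0) + center,
                           c(length / 2, 0) + center),
             length = length, width = width, center = center,
             septum = FALSE, septum_x = NA_real_)
  cl
}

test_that("standardized projection maps landmarks correctly", {
  cl <- make_cell(length = 4)
  pts <- normalize_to_standard_cell(
    data.frame(x_um = c(0, 2, -2), y_um = c(0, 0, 0)), cl, orient = FALSE)
  expect_equal(pts$u, c(0, 1.5, -1.5), tolerance = 1e-9)
  expect_equal(pts$v, c(0, 0, 0), tolerance = 1e-9)

  # off-axis point at half the local half-width maps to v = 0.25
  pts2 <- normalize_to_standard_cell(
    data.frame(x_um = 0, y_um = 0.25), cl, orient = FALSE)
  expect_equal(pts2$v, 0.25, tolerance = 0.01)

  degen <- cl; degen$poles <- rbind(c(0, 0), c(0, 0))
  expect_error(normalize_to_standard_cell(
    data.frame(x_um = 0, y_um = 0), degen), "degenerate")
})

test_that("uniform points give a uniform standardized axial distribution", {
  cl <- make_cell(length = 4)
  set.seed(71)
  n <- 20000
  x <- runif(n, -2, 2); y <- runif(n, -0.5, 0.5)
  keep <- sc_contains(x, y, 4, 1)
  pts <- normalize_to_standard_cell(
    data.frame(x_um = x[keep], y_um = y[keep]), cl, orient = FALSE)
  # central cylindrical part is uniform in u after rescaling
  hist_u <- hist(pts$u[abs(pts$u) < 1.1], breaks = seq(-1.1, 1.1, 0.2),
                 plot = FALSE)$counts
  p <- chisq.test(hist_u)$p.value
  expect_gt(p, 0.001)
})

test_that("heatmaps are normalized and difference heatmaps cancel", {
  set.seed(72)
  pts <- data.frame(u = runif(500, -1.5, 1.5), v = runif(500, -0.5, 0.5))
  g <- build_heatmap(pts)
  expect_equal(dim(g), c(10, 30))
  expect_equal(sum(g), 1, tolerance = 1e-9)
  d <- diff_heatmap(g, g)
  expect_true(all(d == 0))
  one <- build_heatmap(data.frame(u = rep(0.05, 7), v = rep(0.05, 7)))
  expect_equal(sum(one == 0), 299)
  expect_equal(max(one), 1)
  expect_error(build_heatmap(data.frame(u = numeric(0), v = numeric(0))),
               "no points")
})

test_that("demograph rows are sorted by cell length and max-normalized", {
  set.seed(73)
  cell_points <- lapply(c(3.5, 2.0, 2.8), function(L) {
    list(s = runif(200, -L / 2, L / 2), length = L)
  })
  dg <- build_demograph(cell_points)
  expect_equal(nrow(dg), 3)
  expect_equal(attr(dg, "lengths"), c(2.0, 2.8, 3.5))
  expect_true(all(apply(dg, 1, max, na.rm = TRUE) == 1))
  one <- build_demograph(cell_points[1])
  expect_equal(nrow(one), 1)
})

test_that("septal clusters put the demograph maximum at midcell", {
  set.seed(74)
  cell_points <- lapply(seq(2, 3.5, length.out = 8), function(L) {
    list(s = c(rnorm(300, 0, 0.08), runif(100, -L / 2, L / 2)), length = L)
  })
  dg <- build_demograph(cell_points)
  mid <- (ncol(dg) + 1) / 2
  for (i in seq_len(nrow(dg))) {
    expect_lt(abs(which.max(dg[i, ]) - mid), 2)
  }
})

test_that("localization statistics match region proportions", {
  cl <- make_cell(length = 3)
  set.seed(75)
  n <- 20000
  x <- runif(n, -1.5, 1.5); y <- runif(n, -0.5, 0.5)
  keep <- sc_contains(x, y, 3, 1)
  pts <- normalize_to_standard_cell(
    data.frame(x_um = x[keep], y_um = y[keep]), cl)
  st <- compute_localization_stats(pts, cl)
  # region occupancy by area: midcell ~ 0.2 of points (cylindrical part),
  # poles lose some area to curvature, so allow generous tolerance
  expect_lt(abs(st$midcell_prop - 0.2), 0.03)
  expect_lt(abs(st$polar_prop - 0.4), 0.06)
  expect_equal(st$midcell_prop + st$polar_prop +
                 mean(abs(pts$s) > 0.3 & abs(pts$s) < 0.9), 1,
               tolerance = 1e-9)

  # all points at one pole
  pole_pts <- normalize_to_standard_cell(
    data.frame(x_um = rep(1.45, 50), y_um = 0), cl)
  stp <- compute_localization_stats(pole_pts, cl)
  expect_equal(stp$polar_ratio, 0)
  expect_equal(stp$polar_prop, 1)
  expect_error(compute_localization_stats(pts[0, ], cl), "no points")
})

test_that("planted polar asymmetry yields the expected polar ratio", {
  cl <- make_cell(length = 3)
  set.seed(76)
  n <- 10000
  side <- sample(c(-1, 1), n, TRUE, prob = c(0.4, 0.6))
  pts <- normalize_to_standard_cell(
    data.frame(x_um = side * runif(n, 1.0, 1.45), y_um = 0), cl)
  st <- compute_localization_stats(pts, cl)
  expect_lt(abs(st$polar_ratio - 40 / 60), 0.05)
})

test_that("pole orientation puts the lesser-count pole at negative u", {
  cl <- make_cell(length = 3)
  set.seed(77)
  side <- sample(c(-1, 1), 1000, TRUE, prob = c(0.7, 0.3))
  pts <- normalize_to_standard_cell(
    data.frame(x_um = side * runif(1000, 0.5, 1.4), y_um = 0), cl)
  expect_gt(sum(pts$u > 0), sum(pts$u < 0))
})

test_that("loess trend reproduces constants and straight lines", {
  x <- seq(1, 4, length.out = 40)
  cst <- loess_trend(x, rep(2.5, 40))
  expect_equal(cst$fit, rep(2.5, 50), tolerance = 1e-9)
  lin <- loess_trend(x, 2 * x)
  interior <- lin$x > 1.3 & lin$x < 3.7
  expect_equal(lin$fit[interior], 2 * lin$x[interior], tolerance = 1e-6)
  expect_error(loess_trend(1:5, 1:5), "at least 10")
})
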