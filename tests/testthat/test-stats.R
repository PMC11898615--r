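test_that("Vargha-Delaney A matches brute-force pair counting", {
  expect_equal(vargha_delaney_a(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(vargha_delaney_a(c(2, 3), c(0, 1)), 1)
  expect_equal(vargha_delaney_a(c(1, 2), c(0, 3)), 0.5)

  set.seed(91)
  for (i in 1:25) {
    x <- sample(0:5, sample(2:8, 1), TRUE)
    y <- sample(0:5, sample(2:8, 1), TRUE)
    brute <- (sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))) /
      (length(x) * length(y))
    expect_equal(vargha_delaney_a(x, y), brute, tolerance = 1e-12)
  }
  # complementarity for tie-free samples
  x <- rnorm(20); y <- rnorm(15)
  expect_equal(vargha_delaney_a(x, y) + vargha_delaney_a(y, x), 1,
               tolerance = 1e-12)
  expect_error(vargha_delaney_a(numeric(0), 1), "non-empty")
})

test_that("Dunn z matches the hand-rank formula and identical groups give p 1", {
  # groups {1..3},{4..6},{7..9}: rank sums 6, 15, 24; no ties
  dn <- dunn_test(list(a = 1:3, b = 4:6, c = 7:9), adjust = "none")
  se <- sqrt((9 * 10 / 12) * (2 / 3))
  expect_equal(dn$z[dn$comparison == "a - c"], (2 - 8) / se,
               tolerance = 1e-12)
  expect_equal(dn$z[dn$comparison == "a - b"], (2 - 5) / se,
               tolerance = 1e-12)

  dn_same <- suppressWarnings(
    dunn_test(list(a = c(1, 2, 3), b = c(1, 2, 3))))
  expect_equal(dn_same$z, 0)
  expect_equal(dn_same$p_adj, 1)

  expect_error(suppressWarnings(dunn_test(list(a = rep(1, 3),
                                               b = rep(1, 4)))), "identical")
})

test_that("Dunn z^2 equals the Kruskal-Wallis H for two groups", {
  set.seed(92)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(6) + 0.5
    # include ties occasionally
    if (i %% 3 == 0) y[1] <- x[1]
    dn <- suppressWarnings(dunn_test(list(x = x, y = y), adjust = "none"))
    kw <- kruskal_wallis(list(x, y))
    expect_equal(dn$z^2, kw$statistic, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis H matches the direct rank formula", {
  # groups {1,2},{3,4}: ranks 1,2 | 3,4; H = 12/(N(N+1)) * sum n (Rbar-R)^2
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  H_hand <- 12 / (4 * 5) * (2 * (1.5 - 2.5)^2 + 2 * (3.5 - 2.5)^2)
  expect_equal(kw$statistic, H_hand, tolerance = 1e-12)

  ident <- kruskal_wallis(list(c(1, 1), c(1, 1)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  set.seed(93)
  for (i in 1:10) {
    g <- list(rnorm(7), rnorm(9), rnorm(5))
    es <- kruskal_wallis(g)$effect_size
    expect_gte(es, 0); expect_lte(es, 1)
  }
})

test_that("rank tests are invariant under monotone transforms", {
  set.seed(94)
  g <- list(a = rexp(8), b = rexp(10) * 1.5, c = rexp(7) * 2)
  tr <- function(v) log(v + 1) * 3 + 2
  kw1 <- kruskal_wallis(g); kw2 <- kruskal_wallis(lapply(g, tr))
  expect_equal(kw1$statistic, kw2$statistic, tolerance = 1e-12)
  d1 <- dunn_test(g); d2 <- dunn_test(lapply(g, tr))
  expect_equal(d1$z, d2$z, tolerance = 1e-12)
  w1 <- wilcoxon_rank_sum(g$a, g$b)
  w2 <- wilcoxon_rank_sum(tr(g$a), tr(g$b))
  expect_equal(w1$p_value, w2$p_value, tolerance = 1e-12)
})

test_that("Wilcoxon exact enumeration on fully separated small samples", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, 0)         # U for x
  expect_equal(w$p_value, 0.1)         # 2 * 1/20
  same <- wilcoxon_rank_sum(1, 1)
  expect_equal(same$p_value, 1)
})

test_that("Shapiro-Wilk flags gross non-normality and rejects bad input", {
  set.seed(95)
  bimodal <- c(rnorm(100, -5), rnorm(100, 5))
  expect_lt(shapiro_wilk(bimodal)$p_value, 0.001)
  expect_error(shapiro_wilk(rep(1, 10)), "zero variance")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  # under the null, normal data rarely rejects
  pass <- sum(sapply(1:100, function(i) {
    set.seed(9500 + i)
    shapiro_wilk(rnorm(500))$p_value > 0.01
  }))
  expect_gte(pass, 95)
})

test_that("Dunn multiplicity adjustment is applied as requested", {
  set.seed(96)
  g <- list(a = rnorm(10), b = rnorm(10) + 2, c = rnorm(10) + 4)
  raw <- dunn_test(g, adjust = "none")
  holm <- dunn_test(g, adjust = "holm")
  bonf <- dunn_test(g, adjust = "bonferroni")
  expect_equal(holm$p_adj, p.adjust(raw$p_raw, "holm"), tolerance = 1e-15)
  expect_equal(bonf$p_adj, pmin(raw$p_raw * 3, 1), tolerance = 1e-15)
})
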