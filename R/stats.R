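# Nonparametric inference layer: Vargha-Delaney's A, Dunn's test,
# Kruskal-Wallis with effect size, Wilcoxon rank-sum, Shapiro-Wilk.

#' Vargha and Delaney's A effect size
#'
#' `A = (#\{x_i > y_j\} + 0.5 * #\{x_i = y_j\}) / (n_x * n_y)`: the
#' probability that a random value from `x` exceeds one from `y`, ties
#' counting half. 0.5 means stochastic equality.
#'
#' @param x,y numeric samples (non-empty).
#' @return A in [0, 1].
#' @examples
#' vargha_delaney_a(c(2, 3), c(0, 1))  # 1
#' @export
vargha_delaney_a <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  # rank formulation is O((n+m) log(n+m)) and handles ties exactly
  r <- rank(c(x, y))
  r1 <- sum(r[seq_along(x)])
  nx <- length(x); ny <- length(y)
  (r1 / nx - (nx + 1) / 2) / ny
}

#' Kruskal-Wallis rank-sum test with effect size
#'
#' Delegates the tie-corrected H statistic and chi-squared p-value to
#' [stats::kruskal.test()] and adds a rank-based effect size. Two conventions
#' are offered (naming differs across sources; this package's default,
#' `"epsilon2"`, is `(H - k + 1) / (N - k)`, the bias-corrected ratio also
#' known as eta-squared-H; `"rank_epsilon2"` is `H (N + 1) / (N^2 - 1)`).
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @param effect `"epsilon2"` ((H - k + 1)/(N - k), default) or
#'   `"rank_epsilon2"` (H * (N + 1) / (N^2 - 1)).
#' @return list of class `septrack_test`: `statistic` (H), `df`, `p_value`,
#'   `effect_size`, `n`.
#' @export
kruskal_wallis <- function(groups, effect = c("epsilon2", "rank_epsilon2")) {
  effect <- match.arg(effect)
  if (length(groups) < 2) stop("need at least 2 groups")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  N <- length(x); k <- length(groups)
  if (stats::var(x) == 0) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(x, g)
    H <- unname(kt$statistic); p <- kt$p.value
  }
  es <- if (effect == "epsilon2") (H - k + 1) / (N - k)
        else H * (N + 1) / (N^2 - 1)
  es <- min(max(es, 0), 1)
  structure(list(test = "Kruskal-Wallis", statistic = H, df = k - 1,
                 p_value = p, effect_size = es, effect_type = effect,
                 n = lengths(groups)),
            class = "septrack_test")
}

#' Dunn's test of multiple comparisons
#'
#' Pairwise post-hoc comparisons on the pooled mid-ranks:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - T) (1/n_i + 1/n_j))`
#' with tie correction `T = sum(t^3 - t) / (12 (N - 1))`; two-sided p from
#' the standard normal, with a multiplicity adjustment.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2;
#'   with exactly 2 groups a warning is issued).
#' @param adjust p-value adjustment: `"holm"` (default), `"bonferroni"`,
#'   `"BH"` or `"none"`.
#' @param p_threshold significance threshold recorded in the output.
#' @return data.frame of class `dunn_test`: `comparison`, `z`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
dunn_test <- function(groups, adjust = c("holm", "bonferroni", "BH", "none"),
                      p_threshold = 0.05) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (k == 2) warning("Dunn's test with only 2 groups; consider wilcoxon_rank_sum")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  x <- unlist(groups)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)  # mid-ranks
  if (stats::var(x) == 0)
    stop("all pooled values identical: rank variance is zero")
  tie_sizes <- table(x)
  Tcorr <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  Rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  pairs <- utils::combn(k, 2)
  z <- p_raw <- numeric(ncol(pairs))
  lab <- character(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[i] + 1 / n[j]))
    z[c] <- (Rbar[i] - Rbar[j]) / se
    p_raw[c] <- 2 * stats::pnorm(-abs(z[c]))
    lab[c] <- paste(names(groups)[i], "-", names(groups)[j])
  }
  p_adj <- stats::p.adjust(p_raw, method = if (adjust == "none") "none" else adjust)
  res <- data.frame(comparison = lab, z = z, p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj < p_threshold)
  class(res) <- c("dunn_test", "data.frame")
  attr(res, "adjust") <- adjust
  res
}

#' Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Two-sided rank-sum test via [stats::wilcox.test()]: exact enumeration when
#' `n_x * n_y <= 400` and the data are tie-free, otherwise the normal
#' approximation with tie and continuity correction. Also reports
#' Vargha-Delaney's A as the effect size.
#'
#' @param x,y numeric samples (non-empty).
#' @return list of class `septrack_test` with `statistic` (U for x), `p_value`,
#'   `effect_size` (A), `n`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  if (stats::var(c(x, y)) == 0 || isTRUE(all.equal(stats::var(c(x, y)), 0))) {
    return(structure(list(test = "Wilcoxon rank-sum",
                          statistic = length(x) * length(y) / 2,
                          p_value = 1, effect_size = 0.5,
                          n = c(length(x), length(y))),
                     class = "septrack_test"))
  }
  exact <- length(x) * length(y) <= 400 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  structure(list(test = "Wilcoxon rank-sum", statistic = unname(wt$statistic),
                 p_value = min(wt$p.value, 1),
                 effect_size = vargha_delaney_a(x, y),
                 n = c(length(x), length(y))),
            class = "septrack_test")
}

#' Shapiro-Wilk normality test
#'
#' Delegates to [stats::shapiro.test()] (Royston's 1995 approximation).
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @return list of class `septrack_test` with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(x) == 0) stop("constant sample: zero variance")
  st <- stats::shapiro.test(x)
  structure(list(test = "Shapiro-Wilk", statistic = unname(st$statistic),
                 p_value = st$p.value, effect_size = NA_real_,
                 n = length(x)),
            class = "septrack_test")
}

#' @export
print.septrack_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g", x$test, x$statistic,
              x$p_value))
  if (!is.null(x$effect_size) && is.finite(x$effect_size))
    cat(sprintf(", effect size = %.4g", x$effect_size))
  cat(sprintf(" (n = %s)\n", paste(x$n, collapse = ", ")))
  invisible(x)
}
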