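# Shared fixture builders (everything generated in code; no stored data).

# A large, nearly unconfined arena so free-diffusion closed forms apply.
big_cells <- function(seed = 1L, n = 5L) {
  simulate_cell_population(
    sim_cell_config(n_cells = n, length_mean = 30, length_sd = 0.1,
                    width = 15, septum_prob = 0, seed = seed))
}

# Default-geometry cells (the 2.5 x 1 um population).
std_cells <- function(seed = 1L, n = 50L, septum_prob = 0.5) {
  simulate_cell_population(
    sim_cell_config(n_cells = n, septum_prob = septum_prob, seed = seed))
}

# Brute-force max-cardinality / min-total-squared-distance matching oracle
# for one frame pair; mirrors the contract of match_frame_pair.
brute_force_match <- function(px, py, qx, qy, max_link) {
  n <- length(px); m <- length(qx)
  best <- NULL
  d2 <- outer(px, qx, "-")^2 + outer(py, qy, "-")^2
  allowed <- d2 <= max_link^2
  # enumerate assignments via recursion over rows
  rec <- function(i, used, links, card, cost) {
    if (i > n) {
      if (is.null(best) || card > best$card ||
          (card == best$card && cost < best$cost - 1e-15)) {
        best <<- list(links = links, card = card, cost = cost)
      }
      return(invisible())
    }
    rec(i + 1L, used, c(links, NA_integer_), card, cost)  # leave i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && allowed[i, j]) {
        used[j] <- TRUE
        rec(i + 1L, used, c(links, j), card + 1L, cost + d2[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), integer(0), 0L, 0)
  best
}

# Total squared cost of a link vector against coordinates.
link_cost <- function(links, px, py, qx, qy) {
  ok <- !is.na(links)
  sum((px[ok] - qx[links[ok]])^2 + (py[ok] - qy[links[ok]])^2)
}
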