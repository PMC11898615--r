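# Frame-to-frame track linking by optimal bipartite assignment.

#' Solve a (square) linear assignment problem
#'
#' Kuhn-Munkres / Jonker-Volgenant style O(n^3) algorithm with dual
#' potentials; minimizes the total cost of a perfect matching on a square
#' cost matrix. Used internally by [link_tracks()].
#'
#' @param cost square numeric cost matrix (finite values).
#' @return integer vector `a` with `a[i]` = column assigned to row `i`.
#' @keywords internal
solve_lap <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  INF <- .Machine$double.xmax / 4
  # potentials and matching; 0 = unmatched; columns indexed 1..n, row 0 dummy
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[2:(n + 1L)])  # column indices 1..n not yet used
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free + 1L]
      if (any(upd)) {
        minv[free[upd] + 1L] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      jbest <- free[which.min(minv[free + 1L])]
      delta <- minv[jbest + 1L]
      # update potentials along used columns, shrink minv on free ones
      used_j <- which(used) - 1L
      rows <- p[used_j + 1L]
      pos <- rows > 0L
      u[rows[pos]] <- u[rows[pos]] + delta
      v[used_j + 1L] <- v[used_j + 1L] - delta
      minv[free + 1L] <- minv[free + 1L] - delta
      j0 <- jbest
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) a[p[j + 1L]] <- j
  a
}

# Optimal frame-pair assignment with forbidden links and unmatched options.
# Among maximum-cardinality matchings using only pairs with squared distance
# <= max_link^2, returns the one of minimum total squared distance.
# Returns an integer vector of length n_prev: index into the next-frame spots
# or NA (track ends).
match_frame_pair <- function(px, py, qx, qy, max_link) {
  n <- length(px); m <- length(qx)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  d2 <- outer(px, qx, "-")^2 + outer(py, qy, "-")^2
  allowed <- d2 <= max_link^2
  if (!any(allowed)) return(rep(NA_integer_, n))
  # decompose the bipartite graph of allowed links into connected components
  # and solve each component separately (typical components are tiny)
  comp_p <- rep(0L, n); comp_q <- rep(0L, m)
  ncomp <- 0L
  for (i0 in seq_len(n)) {
    if (comp_p[i0] > 0L || !any(allowed[i0, ])) next
    ncomp <- ncomp + 1L
    queue_p <- i0
    while (length(queue_p)) {
      comp_p[queue_p] <- ncomp
      qs <- which(colSums(allowed[queue_p, , drop = FALSE]) > 0 & comp_q == 0L)
      if (!length(qs)) break
      comp_q[qs] <- ncomp
      queue_p <- which(rowSums(allowed[, qs, drop = FALSE]) > 0 & comp_p == 0L)
    }
  }
  link <- rep(NA_integer_, n)
  for (cc in seq_len(ncomp)) {
    ip <- which(comp_p == cc); iq <- which(comp_q == cc)
    if (length(ip) == 1L && length(iq) == 1L) {
      link[ip] <- iq
      next
    }
    link[ip] <- iq[solve_matching(d2[ip, iq, drop = FALSE],
                                  allowed[ip, iq, drop = FALSE], max_link)]
  }
  link
}

# max-cardinality / min-cost matching on one (small) component via the
# augmented square LAP: real-real = d2 (or FORBID), real-dummy / dummy-real
# = K (no link), dummy-dummy = 0. K larger than any total allowed cost makes
# the solver maximize the number of allowed links first.
solve_matching <- function(d2, allowed, max_link) {
  n <- nrow(d2); m <- ncol(d2)
  K <- (sum(d2[allowed]) + max_link^2 + 1)
  FORBID <- K * (n + m + 1)
  sz <- n + m
  cost <- matrix(0, sz, sz)
  rr <- d2
  rr[!allowed] <- FORBID
  cost[seq_len(n), seq_len(m)] <- rr
  cost[seq_len(n), (m + 1L):sz] <- K
  cost[(n + 1L):sz, seq_len(m)] <- K
  a <- solve_lap(cost)
  link <- a[seq_len(n)]
  link[link > m] <- NA_integer_
  bad <- !is.na(link) & !allowed[cbind(seq_len(n), ifelse(is.na(link), 1L, link))]
  link[bad] <- NA_integer_
  link
}

#' Link localizations into tracks
#'
#' Between every pair of consecutive frames, a minimum-total-squared-distance
#' bipartite assignment is computed between the heads of active tracks and
#' the new localizations, with links longer than `max_link` forbidden (among
#' matchings of maximal size, the cheapest is chosen). Unlinked spots start
#' new tracks; no frame gaps are allowed (`max_gap = 0` is the only supported
#' value), so a track not extended in a frame is closed. Tracks shorter than
#' `min_len` frames are discarded. Within each frame, spots are processed
#' sorted by x, then y, so linking is invariant to input order.
#'
#' @param locs localization data.frame (`frame`, `x_um`, `y_um`, optionally
#'   `intensity`, `snr`).
#' @param max_link maximum linking distance (um); default 0.3 (300 nm).
#' @param max_gap allowed frame gap; only 0 is supported.
#' @param min_len minimum track length in frames; default 5.
#' @return track data.frame: `track_id`, `frame`, `x_um`, `y_um` (plus any
#'   extra columns carried through).
#' @examples
#' locs <- data.frame(frame = 0:5, x_um = 0.01 * (0:5), y_um = 0)
#' link_tracks(locs, min_len = 5)
#' @export
link_tracks <- function(locs, max_link = 0.3, max_gap = 0L, min_len = 5L) {
  if (max_link < 0) stop("max_link must be non-negative")
  if (max_gap != 0L) stop("only max_gap = 0 (no frame gaps) is supported")
  if (min_len < 1L) stop("min_len must be >= 1")
  if (nrow(locs) == 0) return(cbind(track_id = integer(0), locs))
  locs <- locs[order(locs$frame, locs$x_um, locs$y_um), , drop = FALSE]
  frames <- sort(unique(locs$frame))
  by_frame <- split(seq_len(nrow(locs)), locs$frame)

  track_of <- integer(nrow(locs))
  next_id <- 1L
  # active tracks: row indices of current heads
  first <- by_frame[[1]]
  track_of[first] <- seq_along(first)
  next_id <- length(first) + 1L
  heads <- first
  for (fi in seq_along(frames)[-1]) {
    cur <- by_frame[[fi]]
    if (frames[fi] != frames[fi - 1] + 1) {
      heads <- integer(0)  # gap in the frame sequence closes all tracks
    }
    link <- match_frame_pair(locs$x_um[heads], locs$y_um[heads],
                             locs$x_um[cur], locs$y_um[cur], max_link)
    matched_cur <- rep(FALSE, length(cur))
    if (length(heads)) {
      ok <- !is.na(link)
      track_of[cur[link[ok]]] <- track_of[heads[ok]]
      matched_cur[link[ok]] <- TRUE
    }
    new <- cur[!matched_cur]
    if (length(new)) {
      track_of[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    heads <- cur
  }

  locs$track_id <- track_of
  tl <- table(track_of)
  keep_ids <- as.integer(names(tl)[tl >= min_len])
  out <- locs[locs$track_id %in% keep_ids, , drop = FALSE]
  if (nrow(out)) {
    # renumber track ids consecutively in order of first appearance
    out <- out[order(out$track_id, out$frame), , drop = FALSE]
    out$track_id <- match(out$track_id, unique(out$track_id))
    rownames(out) <- NULL
  }
  out[, c("track_id", setdiff(names(out), "track_id"))]
}
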