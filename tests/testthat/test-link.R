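test_that("an unambiguous chain links into one track, short chains are dropped", {
  locs <- data.frame(frame = 0:4, x_um = 0.02 * (0:4), y_um = 0)
  tr <- link_tracks(locs, min_len = 5)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 5)
  expect_equal(tr$frame, 0:4)

  locs4 <- data.frame(frame = 0:3, x_um = 0.02 * (0:3), y_um = 0)
  expect_equal(nrow(link_tracks(locs4, min_len = 5)), 0)
})

test_that("links longer than max_link are forbidden", {
  locs <- data.frame(frame = 0:5,
                     x_um = c(0, 0.1, 0.2, 0.9, 1.0, 1.1), y_um = 0)
  tr <- link_tracks(locs, max_link = 0.3, min_len = 3)
  expect_equal(length(unique(tr$track_id)), 2)
  by_track <- split(tr$x_um, tr$track_id)
  expect_true(all(vapply(by_track, function(x) all(diff(x) <= 0.3 + 1e-12),
                         logical(1))))
})

test_that("no track contains two spots in one frame; frames are consecutive", {
  set.seed(31)
  locs <- data.frame(frame = rep(0:19, each = 3),
                     x_um = runif(60, 0, 2), y_um = runif(60, 0, 2))
  tr <- link_tracks(locs, max_link = 0.5, min_len = 2)
  for (tid in unique(tr$track_id)) {
    fr <- tr$frame[tr$track_id == tid]
    expect_false(any(duplicated(fr)))
    expect_true(all(diff(sort(fr)) == 1))
  }
})

test_that("linking is invariant to input row order", {
  set.seed(32)
  locs <- data.frame(frame = rep(0:9, each = 4),
                     x_um = runif(40, 0, 3), y_um = runif(40, 0, 3))
  t1 <- link_tracks(locs, max_link = 0.6, min_len = 2)
  perm <- sample(nrow(locs))
  t2 <- link_tracks(locs[perm, ], max_link = 0.6, min_len = 2)
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})

test_that("frame-pair assignment matches the brute-force oracle", {
  set.seed(33)
  for (inst in 1:100) {
    n <- sample(0:4, 1); m <- sample(0:4, 1)
    px <- runif(n); py <- runif(n)
    qx <- runif(m); qy <- runif(m)
    max_link <- runif(1, 0.2, 0.8)
    got <- match_frame_pair(px, py, qx, qy, max_link)
    if (n == 0) { expect_length(got, 0); next }
    if (m == 0) { expect_true(all(is.na(got))); next }
    oracle <- brute_force_match(px, py, qx, qy, max_link)
    expect_equal(sum(!is.na(got)), oracle$card)
    expect_equal(link_cost(got, px, py, qx, qy), oracle$cost,
                 tolerance = 1e-12)
  }
})

test_that("parameter validation", {
  expect_error(link_tracks(data.frame(frame = 0, x_um = 0, y_um = 0),
                           max_link = -1), "max_link")
  expect_error(link_tracks(data.frame(frame = 0, x_um = 0, y_um = 0),
                           max_gap = 1), "max_gap")
})
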