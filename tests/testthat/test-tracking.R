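rg <- function(x, y) data.frame(x_um = x, y_um = y)

test_that("link_pair obeys the distance gate", {
  a <- rg(1.0, 1.0); b <- rg(1.3, 1.0)
  asn <- link_pair(a, b, max_link_dist = 1)
  expect_equal(nrow(asn$matches), 1)
  expect_equal(asn$total_cost, 0.3, tolerance = 1e-9)

  far <- rg(2.5, 1.0)
  asn2 <- link_pair(a, far, max_link_dist = 1)
  expect_equal(nrow(asn2$matches), 0)
  expect_equal(asn2$unmatched_t, 1L)
  expect_equal(asn2$unmatched_t1, 1L)

  empty <- link_pair(rg(numeric(0), numeric(0)), b, 1)
  expect_equal(nrow(empty$matches), 0)
})

test_that("crossing pairs match globally, not greedily", {
  # greedy would link a1 to its nearest b1 and strand the rest expensively
  a <- rg(c(0, 0.6), c(0, 0))
  b <- rg(c(0.5, 1.0), c(0, 0))
  asn <- link_pair(a, b, max_link_dist = 1)
  oracle <- oracle_assignment(a, b, 1)
  expect_equal(assignment_cost(asn, 1), oracle$cost, tolerance = 1e-9)
  expect_equal(nrow(asn$matches), 2)
})

test_that("assignment equals the brute-force enumeration oracle (n <= 6)", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    a <- rg(runif(n, 0, 4), runif(n, 0, 4))
    b <- rg(runif(m, 0, 4), runif(m, 0, 4))
    gate <- runif(1, 0.5, 2)
    asn <- link_pair(a, b, gate)
    if (n == 0 || m == 0) {
      expect_equal(nrow(asn$matches), 0)
      next
    }
    oracle <- oracle_assignment(a, b, gate)
    expect_equal(assignment_cost(asn, gate), oracle$cost, tolerance = 1e-9)
    # matched pairs all within the gate
    if (nrow(asn$matches) > 0) {
      d <- sqrt((a$x_um[asn$matches[, 1]] - b$x_um[asn$matches[, 2]])^2 +
                  (a$y_um[asn$matches[, 1]] - b$y_um[asn$matches[, 2]])^2)
      expect_true(all(d <= gate + 1e-12))
    }
  }
})

test_that("global assignment never costs more than greedy matching", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 5
    a <- rg(runif(n, 0, 3), runif(n, 0, 3))
    b <- rg(runif(n, 0, 3), runif(n, 0, 3))
    gate <- 1.5
    asn <- link_pair(a, b, gate)
    # greedy nearest-neighbour
    d <- sqrt(outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2)
    used <- rep(FALSE, n); greedy_cost <- 0; matched <- 0
    for (i in seq_len(n)) {
      j <- which(!used & d[i, ] <= gate)
      if (length(j) == 0) next
      j <- j[which.min(d[i, j])]
      used[j] <- TRUE
      greedy_cost <- greedy_cost + d[i, j]
      matched <- matched + 1
    }
    greedy_total <- greedy_cost + gate * 2 * (n - matched)
    expect_lte(assignment_cost(asn, gate), greedy_total + 1e-9)
  }
})

test_that("build_tracks chains detections into gap-free trajectories", {
  # one spot at constant velocity over 97 frames
  det <- data.frame(frame = 1:97, x_um = 0.05 * (0:96), y_um = 2)
  tr <- build_tracks(det, max_link_dist = 1)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 97)
  expect_identical(tr$frame, 1:97)

  # a second organelle appearing at frame 50 starts a new track
  det2 <- rbind(det, data.frame(frame = 50:97, x_um = 10, y_um = 10))
  tr2 <- build_tracks(det2, max_link_dist = 1)
  expect_equal(length(unique(tr2$track_id)), 2)
  born <- tapply(tr2$frame, tr2$track_id, min)
  expect_setequal(as.numeric(born), c(1, 50))
  # frames strictly consecutive within every track
  for (tid in unique(tr2$track_id))
    expect_true(all(diff(tr2$frame[tr2$track_id == tid]) == 1))
})

test_that("track birth/death bookkeeping balances region counts", {
  set.seed(5)
  frames <- list()
  for (t in 1:8) {
    k <- sample(2:5, 1)
    frames[[t]] <- data.frame(frame = t, x_um = runif(k, 0, 10),
                              y_um = runif(k, 0, 10))
  }
  det <- do.call(rbind, frames)
  tr <- build_tracks(det, max_link_dist = 0.8)
  n_tracks <- length(unique(tr$track_id))
  first_frame <- nrow(frames[[1]])
  births_later <- n_tracks - first_frame
  # every detection belongs to exactly one track sample
  expect_equal(nrow(tr), nrow(det))
  expect_gte(births_later, 0)
})
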