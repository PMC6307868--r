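mk_track <- function(x, y = NULL, frames = NULL) {
  if (is.null(y)) y <- rep(0, length(x))
  if (is.null(frames)) frames <- seq_along(x)
  data.frame(track_id = 1L, frame = frames, x_um = x, y_um = y)
}

test_that("track statistics reproduce the published self-consistent pair", {
  # 24 moving intervals of 0.15 um then pauses over a 480 s session
  x <- cumsum(c(0, rep(0.15, 24), rep(0, 72)))
  s <- track_statistics(mk_track(x), frame_interval = 5)
  expect_equal(s$total_distance, 3.6, tolerance = 1e-9)
  expect_equal(s$duration_s, 480)
  expect_equal(s$avg_speed, 0.0075, tolerance = 1e-9)
  expect_equal(as.character(s$motility_class), "very_short")
})

test_that("track statistics handle degenerate and reversing motion", {
  s0 <- track_statistics(mk_track(rep(1, 10)))
  expect_equal(s0$total_distance, 0)
  expect_equal(s0$net_distance, 0)
  expect_equal(s0$max_speed, 0)
  expect_equal(as.character(s0$motility_class), "static")

  # +2 um then -2 um in 0.5-um steps: total 4, net 0
  x <- cumsum(c(0, rep(0.5, 4), rep(-0.5, 4)))
  s <- track_statistics(mk_track(x), frame_interval = 5)
  expect_equal(s$total_distance, 4)
  expect_equal(s$net_distance, 0)

  # sub-floor jitter accumulates no distance but appears in max_speed
  j <- mk_track(cumsum(c(0, rep(0.05, 9))))
  sj <- track_statistics(j, frame_interval = 5, displacement_floor = 0.1)
  expect_equal(sj$total_distance, 0)
  expect_equal(sj$max_speed, 0.01, tolerance = 1e-9)
  expect_error(track_statistics(mk_track(1)), "at least 2")
})

test_that("motility classification uses half-open published intervals", {
  expect_equal(as.character(classify_motility(0.5)), "static")
  expect_equal(as.character(classify_motility(1.0)), "very_short")
  expect_equal(as.character(classify_motility(5.0)), "short")
  expect_equal(as.character(classify_motility(9.999)), "short")
  expect_equal(as.character(classify_motility(10.0)), "long")
  expect_equal(as.character(classify_motility(12)), "long")
  expect_error(classify_motility(-1), "non-negative")
})

test_that("motility identities hold on random tracks", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    tr <- mk_track(cumsum(rnorm(n, 0, 0.3)), cumsum(rnorm(n, 0, 0.3)))
    s <- track_statistics(tr, frame_interval = 5)
    expect_gte(s$total_distance, s$net_distance - 1e-12)
    expect_gte(s$net_distance, 0)
    expect_equal(s$avg_speed * s$duration_s, s$total_distance,
                 tolerance = 1e-12)
    expect_gte(s$max_speed, s$avg_speed - 1e-12)
  }
})

test_that("cohort summary fractions sum to one and ECDFs are proper", {
  tracks <- rbind(
    cbind(mk_track(cumsum(c(0, rep(0.5, 30), rep(0, 20)))), id = 1),
    cbind(mk_track(rep(0, 50)), id = 2),
    cbind(mk_track(cumsum(c(0, rep(0.15, 20), rep(0, 29)))), id = 3))
  tracks$track_id <- tracks$id
  tracks$organelle <- "PO"
  mt <- motility_table(tracks, frame_interval = 5)
  co <- cohort_summary(mt)
  expect_equal(sum(co$class_fractions), 1)
  expect_equal(co$n_tracks, 3)
  e <- co$ecdf_distance
  q <- seq(0, 20, by = 0.5)
  expect_true(all(diff(e(q)) >= 0))       # nondecreasing
  expect_equal(e(1e9), 1)                 # reaches 1
  single <- motility_table(mk_track(rep(0, 5)), frame_interval = 5)
  single$organelle <- "PO"
  expect_equal(unname(cohort_summary(single)$class_fractions),
               c(1, 0, 0, 0))
  expect_error(cohort_summary(mt[0, ]), "at least one")
})

test_that("directionality signs follow the change in distance to soma", {
  masks <- corridor_masks()
  gmap <- geodesic_map(masks, pixel_size = 0.08)
  # corridor runs along row 60, columns ~40..115; x = (col-1)*0.08.
  # endpoints sit beyond the seeded zone so offsets cancel in differences
  out <- data.frame(frame = 1:2, x_um = c(60, 97.5) * 0.08,
                    y_um = c(59, 59) * 0.08)
  expect_equal(directionality(out, masks, gmap = gmap), 3, tolerance = 0.2)
  inw <- out[2:1, ]; inw$frame <- 1:2
  expect_equal(directionality(inw, masks, gmap = gmap), -3, tolerance = 0.2)
  back <- data.frame(frame = 1:3, x_um = c(60, 95, 60.2) * 0.08,
                     y_um = rep(59, 3) * 0.08)
  expect_lt(abs(directionality(back, masks, gmap = gmap)), 0.25)
  outside <- data.frame(frame = 1:2, x_um = c(0.1, 0.2), y_um = c(0.1, 0.2))
  expect_error(directionality(outside, masks, gmap = gmap), "outside")
})

test_that("temporal projection sums frames pixel-wise", {
  f <- matrix(3, 8, 8)
  expect_equal(temporal_projection(list(f, f)), matrix(6, 8, 8))
  mv <- list(matrix(0, 8, 8), matrix(0, 8, 8))
  mv[[1]][2, 2] <- 5; mv[[2]][6, 7] <- 5
  pr <- temporal_projection(mv)
  expect_true(pr[2, 2] > 0 && pr[6, 7] > 0)
})

test_that("kymographs show static columns and sloped moving traces", {
  n <- 64; n_frames <- 20
  path <- cbind(rep(32, 50), 8:57)
  mk_frames <- function(col_of_t)
    lapply(seq_len(n_frames), function(t)
      neuromot:::stamp_spot(matrix(0, n, n), 32, col_of_t(t), 100, 1.5))
  static <- mk_frames(function(t) 20)
  k <- make_kymograph(static, path, width = 5)
  expect_equal(nrow(k$image), n_frames)
  peaks <- apply(k$image, 1, which.max)
  expect_true(all(peaks == peaks[1]))                  # vertical line

  moving <- mk_frames(function(t) 10 + t)              # 1 px per frame
  km <- make_kymograph(moving, path, width = 5)
  slopes <- diff(apply(km$image, 1, which.max))
  expect_equal(median(slopes), 1)

  # off-path spot captured through the perpendicular maximum
  off <- lapply(seq_len(3), function(t)
    neuromot:::stamp_spot(matrix(0, n, n), 34, 20, 100, 1.5))
  k5 <- make_kymograph(off, path, width = 5)
  k1 <- make_kymograph(off, path, width = 1)
  expect_gt(max(k5$image), max(k1$image))
  expect_error(make_kymograph(static, cbind(c(1, 200), c(1, 10)), 5),
               "exits")
})

test_that("kymograph line readout converts geometry to physical units", {
  v <- rbind(c(0, 0), c(20, 25))
  r <- kymo_readout(v, pixel_size = 0.08, frame_interval = 5)
  expect_equal(r$segment_velocities_um_s, 0.02, tolerance = 1e-12)
  expect_equal(r$total_distance_um, 2.0, tolerance = 1e-12)
  vert <- rbind(c(0, 10), c(10, 10))
  expect_equal(kymo_readout(vert)$segment_velocities_um_s, 0)
  two <- rbind(c(0, 0), c(10, 12), c(20, 2))
  expect_equal(kymo_readout(two)$total_distance_um, (12 + 10) * 0.08,
               tolerance = 1e-12)
  expect_error(kymo_readout(rbind(c(0, 0), c(0, 5))), "zero-duration")
  expect_error(kymo_readout(rbind(c(5, 0), c(1, 5))), "monotone")
})

test_that("kymograph readout agrees with track statistics within quantization", {
  # constant-velocity spot: 0.5 um per 5 s frame along a straight path
  n <- 128; n_frames <- 12
  path <- cbind(rep(64, 110), 9:118)
  frames <- lapply(seq_len(n_frames), function(t)
    neuromot:::stamp_spot(matrix(100, n, n), 64, 10 + (t - 1) * 6.25, 900,
                          1.9))
  k <- make_kymograph(frames, path, width = 5)
  peaks <- apply(k$image, 1, which.max)
  line <- cbind(seq_len(n_frames) - 1, peaks)
  speed_kymo <- mean(kymo_readout(line, 0.08, 5)$segment_velocities_um_s)
  det <- do.call(rbind, lapply(seq_len(n_frames), function(t)
    detect_regions(frames[[t]], matrix(TRUE, n, n), frame_index = t)))
  tr <- build_tracks(det, max_link_dist = 1)
  s <- track_statistics(tr, frame_interval = 5)
  quant <- 0.08 / 5                       # one pixel per frame interval
  expect_lt(abs(speed_kymo - s$max_speed), quant + 1e-9)
})
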