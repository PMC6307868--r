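test_that("constant images give exactly zero ridge strength", {
  r <- frangi_response(matrix(7, 64, 64))
  expect_true(all(r$strength == 0))
})

test_that("frangi enhances an analytic Gaussian ridge and is rotation-tolerant", {
  img <- ridge_image(n = 101, sigma_ridge = 2, theta = 0)
  r <- frangi_response(img, frangi_params(scales = c(1, 2, 3, 4)))
  ctr <- 51
  on_axis <- r$strength[ctr, 51]
  off_axis <- r$strength[ctr + 6, 51]
  expect_gte(on_axis, 5 * off_axis)
  # orientation at the centerline is along the ridge (columns here)
  expect_lt(abs(sin(r$orientation[ctr, 51])), 0.3)

  img30 <- ridge_image(n = 101, sigma_ridge = 2, theta = pi / 6)
  r30 <- frangi_response(img30, frangi_params(scales = c(1, 2, 3, 4)))
  expect_lt(abs(r30$strength[51, 51] - on_axis) / on_axis, 0.10)
})

test_that("hysteresis keeps only low-connected components with a seed", {
  # synthetic thinned ridge map: one strong segment, one weak-only segment
  strength <- matrix(0, 30, 40)
  strength[15, 5:20] <- 10       # contains seeds
  strength[15, 21:25] <- 4       # weak but connected to the seed run
  strength[5, 5:15] <- 4         # weak component with no seed
  rm_ <- structure(list(strength = strength,
                        orientation = matrix(0, 30, 40),
                        scales_used = 1), class = "ridge_map")
  mask <- trace_neurites(rm_, low = 3, high = 8, neurite_width_um = 0)
  expect_true(all(mask[15, 5:25]))
  expect_false(any(mask[5, 5:15]))        # excluded: no seed
  # all-below-low gives an empty mask
  rm0 <- structure(list(strength = strength * 0 + 1,
                        orientation = matrix(0, 30, 40),
                        scales_used = 1), class = "ridge_map")
  expect_false(any(trace_neurites(rm0, low = 3, high = 8,
                                  neurite_width_um = 0)))
  expect_error(trace_neurites(rm_, low = 9, high = 8), "low <= high")
})

test_that("hysteresis output satisfies the set-membership invariants", {
  set.seed(42)
  for (rep in 1:5) {
    strength <- matrix(runif(60 * 60), 60, 60)^3 * 10
    rm_ <- structure(list(strength = strength,
                          orientation = matrix(runif(3600, 0, pi), 60),
                          scales_used = 1), class = "ridge_map")
    low <- 2; high <- 6
    mask <- trace_neurites(rm_, low = low, high = high,
                           neurite_width_um = 0)
    thinned <- attr(mask, "thinned")
    # every kept pixel has thinned strength >= low
    expect_true(all(thinned[mask] >= low))
    # every kept component contains at least one seed (>= high)
    lab <- label_components8(mask)
    if (max(lab) > 0) {
      for (l in seq_len(max(lab)))
        expect_true(any(thinned[lab == l] >= high))
    }
    # nothing >= high is discarded
    expect_true(all(mask[thinned >= high]))
  }
})

test_that("soma detection finds the largest blob and fails on blanks", {
  # disk r = 10 um at 0.08 um/px plus thin bright ridges
  n <- 512
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  disk <- (rows - 256)^2 + (cols - 256)^2 <= 125^2
  img <- 100 + 300 * disk
  img[abs(rows - cols) < 4] <- 350               # diagonal ridge
  soma <- detect_soma(img)
  expect_gte(sum(soma & disk) / sum(disk), 0.90)
  expect_lt(abs(sum(soma) - pi * 125^2) / (pi * 125^2), 0.10)

  disk2 <- (rows - 100)^2 + (cols - 420)^2 <= 50^2
  two <- 100 + 300 * (disk | disk2)
  soma2 <- detect_soma(two)
  expect_gte(sum(soma2 & disk) / sum(disk), 0.80)  # larger disk chosen
  expect_lt(sum(soma2 & disk2) / sum(disk2), 0.10)

  expect_error(detect_soma(matrix(5, 256, 256)),
               class = "neuromot_no_soma")
})

test_that("mask finalization subtracts the soma and keeps disjointness", {
  cand <- matrix(FALSE, 40, 40); cand[20, 5:35] <- TRUE
  soma <- matrix(FALSE, 40, 40); soma[15:25, 15:25] <- TRUE
  m <- finalize_masks(cand, soma, soma_margin_px = 0)
  expect_false(any(m$soma_mask & m$neurite_mask))
  expect_false(any(m$neurite_mask[20, 15:25]))     # overlap goes to soma
  expect_true(all(m$neurite_mask[20, 5:14]))

  far_soma <- matrix(FALSE, 40, 40); far_soma[2:4, 2:4] <- TRUE
  m2 <- finalize_masks(cand, far_soma, soma_margin_px = 0)
  expect_identical(which(m2$neurite_mask), which(cand))  # disjoint: unchanged

  m3 <- finalize_masks(matrix(FALSE, 40, 40), soma)
  expect_false(any(m3$neurite_mask))
  expect_true(any(m3$soma_mask))
})

test_that("segmentation recovers planted neurites on a rendered neuron", {
  cfg <- imaging_config()
  g <- make_geometry(cfg, 5, seed = 21)
  gt <- sample_tracks(g, motility_preset("control-PO"), 25, cfg, seed = 22)
  st <- render_timelapse(g, po_tracks = gt, config = cfg, seed = 23)
  masks <- segment_neuron(st)
  cl <- neuromot:::.centerline_raster(g)
  gm <- geometry_masks(g)
  near_soma <- dilate_disc(gm$soma, 14)
  coverage <- mean((masks$neurite_mask | near_soma)[which(cl)])
  expect_gte(coverage, 0.95)
  dmap <- EBImage::distmap(matrix(as.numeric(!cl), nrow(cl)))
  false_frac <- mean(dmap[masks$neurite_mask] > 1.2 / 0.08)
  expect_lte(false_frac, 0.02)
  # soma recovery within 10% of the planted disk area
  expect_lt(abs(sum(masks$soma_mask) - pi * 125^2) / (pi * 125^2), 0.10)
})
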