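test_that("geometry is deterministic, feasible, and respects the soma", {
  cfg <- tiny_config()
  g1 <- tiny_geometry(seed = 3)
  g2 <- tiny_geometry(seed = 3)
  expect_identical(g1$neurite_paths, g2$neurite_paths)

  g0 <- make_geometry(cfg, n_neurites = 0L, seed = 1)
  expect_length(g0$neurite_paths, 0)

  for (i in seq_along(g1$neurite_paths)) {
    p <- g1$neurite_paths[[i]]
    r <- sqrt(rowSums((p - rep(g1$soma_center, each = nrow(p)))^2))
    expect_equal(r[1], g1$soma_radius_px, tolerance = 1e-6) # starts on boundary
    expect_true(all(r[-1] > g1$soma_radius_px))             # never re-enters
    expect_gte(neurite_arclength(g1, i)$length_um, 12)
  }
})

test_that("rasterized soma disk area matches the analytic area within 2%", {
  g <- make_geometry(imaging_config(), n_neurites = 0L, seed = 1)
  m <- geometry_masks(g)
  analytic <- pi * 10^2
  expect_lt(abs(sum(m$soma) * 0.08^2 - analytic) / analytic, 0.02)
})

test_that("degenerate class mixture plants only static tracks", {
  g <- tiny_geometry(seed = 2)
  pre <- motility_preset(class_probs = c(1, 0, 0, 0), run_speed = 0.1)
  gt <- sample_tracks(g, pre, 5, tiny_config(), seed = 4)
  expect_true(all(gt$summary$planted_total_distance < 1))
  expect_true(all(gt$summary$planted_class == "static"))
})

test_that("planted distances re-sum from steps and respect class bounds", {
  cfg <- imaging_config()
  g <- make_geometry(cfg, 5, seed = 11)
  pre <- motility_preset("control-PO")
  gt <- sample_tracks(g, pre, 25, cfg, seed = 12)
  b <- pre$class_distance_bounds
  for (tid in gt$summary$track_id) {
    s <- gt$table$s_um[gt$table$track_id == tid]
    steps <- abs(diff(s))
    resum <- sum(steps)
    expect_equal(resum, gt$summary$planted_total_distance[tid],
                 tolerance = 1e-9)
    k <- gt$summary$planted_class[tid]
    expect_gte(resum, b[k, 1])
    expect_lt(resum, b[k, 2])
    # displacement-floor guarantee: no planted step in (0, oscillation_step)
    nz <- steps[steps > 1e-12]
    if (length(nz)) expect_gte(min(nz), pre$oscillation_step - 1e-9)
  }
  # long-range tracks move at the preset run speed
  long_ids <- gt$summary$track_id[gt$summary$planted_class == "long"]
  for (tid in long_ids) {
    s <- gt$table$s_um[gt$table$track_id == tid]
    expect_equal(max(abs(diff(s))) / cfg$frame_interval, pre$run_speed,
                 tolerance = 1e-9)
  }
})

test_that("planted class mixture and cohort mean distances match the presets", {
  cfg <- imaging_config()
  draws <- list(); draws2 <- list()
  for (s in 1:40) {
    g <- make_geometry(cfg, 5, seed = 300 + s)
    draws[[s]] <- sample_tracks(g, motility_preset("control-PO"), 25, cfg,
                                seed = 400 + s)$summary
    draws2[[s]] <- sample_tracks(g, motility_preset("acbd5-PO"), 25, cfg,
                                 seed = 500 + s)$summary
  }
  ctrl <- do.call(rbind, draws)
  acbd <- do.call(rbind, draws2)
  n <- nrow(ctrl)
  expect_gte(n, 1000)
  p <- c(0.01, 0.59, 0.30, 0.10)
  fr <- as.numeric(table(factor(ctrl$planted_class,
                                motility_class_levels()))) / n
  for (k in 1:4) {
    se <- sqrt(p[k] * (1 - p[k]) / n)
    expect_lt(abs(fr[k] - p[k]), 3 * se + 1e-12)
  }
  # cohort mean planted distances near the published 5.6 / 3.6 um
  expect_lt(abs(mean(ctrl$planted_total_distance) - 5.6) / 5.6, 0.20)
  expect_lt(abs(mean(acbd$planted_total_distance) - 3.6) / 3.6, 0.20)
})

test_that("rendering is a pure function of inputs and seed", {
  cfg <- tiny_config()
  g <- tiny_geometry(seed = 5)
  static <- motility_preset(class_probs = c(1, 0, 0, 0), run_speed = 0.1)
  gt <- sample_tracks(g, static, 3, cfg, seed = 6, soma_offset = 1.5)
  st1 <- render_timelapse(g, po_tracks = gt, config = cfg, seed = 9)
  st2 <- render_timelapse(g, po_tracks = gt, config = cfg, seed = 9)
  expect_identical(st1$stacks, st2$stacks)
})

test_that("noise-free static spot renders with sub-0.05-px centroid error", {
  cfg <- tiny_config(n_frames = 6L)
  g <- tiny_geometry(seed = 5)
  pre <- motility_preset(class_probs = c(1, 0, 0, 0), run_speed = 0.1)
  gt <- sample_tracks(g, pre, 1, cfg, seed = 3, soma_offset = 1.5)
  gt$table$s_um[] <- gt$table$s_um[1]           # freeze in place
  pt <- neurite_arclength(g, gt$summary$neurite_index[1])$point_at(
    gt$table$s_um[1])
  gt$table$row[] <- pt$row; gt$table$col[] <- pt$col
  np <- noise_params(poisson = FALSE, read_sigma = 0)
  st <- render_timelapse(g, po_tracks = gt, config = cfg, noise = np,
                         seed = 1)
  bg <- neuromot:::render_background(g, np)
  spot <- matrix(as.numeric(st$stacks$PO[[1]]), 256) - bg
  idx <- which(spot > 0.01 * max(spot), arr.ind = TRUE)
  w <- spot[idx]
  expect_lt(abs(sum(w * idx[, 1]) / sum(w) - pt$row), 0.05)
  expect_lt(abs(sum(w * idx[, 2]) / sum(w) - pt$col), 0.05)
})

test_that("fixture round trip is bit-exact including metadata", {
  cfg <- tiny_config(n_frames = 3L, shape = 64L)
  g <- make_geometry(cfg, n_neurites = 0L, seed = 1, soma_radius = 1.5)
  st <- render_timelapse(g, po_tracks = NULL, mito_tracks = NULL,
                         config = cfg, seed = 2)
  # no tracks: render background-only PO channel manually
  st$stacks$PO <- lapply(1:3, function(i)
    matrix(as.integer(rpois(64 * 64, 100)), 64))
  dir <- withr::local_tempdir()
  write_fixture(st, dir)
  back <- read_fixture(dir)
  expect_identical(back$stacks$PO, st$stacks$PO)
  expect_identical(back$config$pixel_size, cfg$pixel_size)
  expect_identical(back$config$frame_interval, cfg$frame_interval)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_identical(gt$seed, 2L)
})

test_that("fixture round trip preserves tracks and ground truth", {
  cfg <- tiny_config(n_frames = 4L)
  g <- tiny_geometry(seed = 7)
  static <- motility_preset(class_probs = c(1, 0, 0, 0), run_speed = 0.1)
  gt <- sample_tracks(g, static, 3, cfg, seed = 8, soma_offset = 1.5)
  st <- render_timelapse(g, po_tracks = gt, config = cfg, seed = 9)
  dir <- withr::local_tempdir()
  write_fixture(st, dir)
  back <- read_fixture(dir)
  expect_identical(back$stacks$PO, st$stacks$PO)
  expect_equal(nrow(back$truth$tracks), 3 * 4)
  expect_equal(sort(unique(back$truth$tracks$planted_class)),
               sort(unique(gt$summary$planted_class)))
  js <- back$truth$json
  expect_equal(js$po_summary$planted_total_distance,
               gt$summary$planted_total_distance)
})

test_that("contact planting honours degenerate fractions and clearance", {
  cfg <- imaging_config(n_frames = 2, frame_shape = c(1024L, 1024L))
  g <- make_geometry(cfg, n_neurites = 5L, seed = 31, neurite_length = 60)
  mito <- data.frame(neurite = rep(1:5, each = 4),
                     s_start = rep(c(5, 15, 25, 35), 5),
                     s_end = rep(c(8, 18, 28, 38), 5))
  all_in <- plant_contacts(30, mito, g, contact_preset(contact_fraction = 1),
                           seed = 1)
  expect_true(all(all_in$contact))
  # every contact PO centre lies inside a footprint
  for (i in seq_len(nrow(all_in))) {
    fp <- mito[mito$neurite == all_in$neurite[i], ]
    expect_true(any(all_in$s_um[i] >= fp$s_start &
                      all_in$s_um[i] <= fp$s_end))
  }
  none <- plant_contacts(20, mito, g, contact_preset(contact_fraction = 0),
                         seed = 2)
  expect_false(any(none$contact))
  for (i in seq_len(nrow(none))) {
    fp <- mito[mito$neurite == none$neurite[i], ]
    gap <- pmax(fp$s_start - none$s_um[i], none$s_um[i] - fp$s_end)
    expect_gte(min(gap), 1)          # >= clearance from every footprint
  }
})

test_that("fixed-neuron renderer plants exact counts and blank when empty", {
  cfg <- imaging_config(n_frames = 2, frame_shape = c(1024L, 1024L))
  spec <- fixed_neuron_spec(soma_po_count = 30, neurite_po_count = 10,
                            soma_po_area = 30 * 0.12,
                            neurite_po_area = 10 * 0.09)
  fx <- render_fixed_neuron(spec, cfg, seed = 3)
  expect_equal(sum(fx$truth$spots$region == "soma"), 30)
  expect_equal(sum(fx$truth$spots$region == "neurite"), 10)

  blank <- render_fixed_neuron(
    fixed_neuron_spec(soma_po_count = 0, neurite_po_count = 0,
                      soma_po_area = 0, neurite_po_area = 0),
    cfg, seed = 4)
  po <- blank$stacks$PO[[1]]
  np <- noise_params()
  expect_lt(max(po), np$background + 8 * sqrt(np$background + np$read_sigma^2))
  expect_equal(nrow(blank$truth$spots), 0)
})
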