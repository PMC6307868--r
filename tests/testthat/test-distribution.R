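test_that("proximal region is a geodesic strip of the expected area", {
  # straight corridor ~76 px long (6.1 um) x 7 px wide starting at the soma
  masks <- corridor_masks(n = 120, soma_r = 15, width = 7)
  part <- proximal_region(masks, length = 3, pixel_size = 0.08)
  expect_false(any(part$soma & part$proximal))
  # analytic strip: (3 um + the 14-px seeded band) x 7 px corridor width
  strip <- (3 + 14 * 0.08) * 7 * 0.08
  expect_lt(abs(part$proximal_area_um2 - strip) / strip, 0.15)
  # a cutoff beyond the corridor length includes the whole corridor
  whole <- proximal_region(masks, length = 50, pixel_size = 0.08)
  expect_equal(sum(whole$proximal), sum(masks$neurite_mask))
  expect_error(proximal_region(
    structure(list(soma_mask = matrix(FALSE, 4, 4),
                   neurite_mask = matrix(TRUE, 4, 4)),
              class = "segmentation_masks")), "empty soma")
})

test_that("distribution summary counts regions by centroid membership", {
  masks <- corridor_masks()
  part <- proximal_region(masks, length = 30, pixel_size = 0.08)
  det <- data.frame(row = c(60, 60, 60), col = c(25, 50, 80),
                    area_um2 = c(0.2, 0.1, 0.15))
  s <- distribution_summary(det, part)
  expect_equal(s$po_count[s$region == "soma"], 1)
  expect_equal(s$po_count[s$region == "proximal_neurites"], 2)
  expect_equal(s$po_area_um2[s$region == "proximal_neurites"], 0.25)
  expect_true(all(s$percent_area >= 0 & s$percent_area <= 100, na.rm = TRUE))
  empty <- distribution_summary(det[0, ], part)
  expect_true(all(empty$po_count == 0))
  expect_true(all(empty$po_area_um2 == 0))
})

test_that("contact logic follows overlap-or-adjacency of binarized masks", {
  lab <- matrix(0L, 40, 40)
  lab[10:12, 10:12] <- 1L        # PO touching the mito (adjacent)
  lab[30:32, 30:32] <- 2L        # PO far away
  po <- data.frame(label = c(1L, 2L), row = c(11, 31), col = c(11, 31))
  attr(po, "labels") <- lab
  mito <- matrix(FALSE, 40, 40); mito[10:12, 13:20] <- TRUE  # 8-adjacent
  analysis <- matrix(TRUE, 40, 40)
  cs <- contact_fraction(po, mito, analysis, dilate_px = 1)
  expect_equal(cs$n_po_total, 2)
  expect_equal(cs$n_po_contact, 1)
  expect_equal(cs$contact_fraction, 0.5)
  # all POs overlapping -> 1; none near -> 0
  mito_all <- matrix(TRUE, 40, 40)
  expect_equal(contact_fraction(po, mito_all, analysis)$contact_fraction, 1)
  mito_none <- matrix(FALSE, 40, 40); mito_none[1, 40] <- TRUE
  expect_equal(contact_fraction(po, mito_none, analysis)$contact_fraction, 0)
  expect_error(contact_fraction(po, mito, matrix(FALSE, 40, 40)),
               "undefined contact fraction")
})

test_that("planted contacts are recovered through the full detection chain", {
  fx <- make_contact_fixture(contact_preset("contact-control"), n_po = 60,
                             seed = 3)
  cs <- analyze_contacts(fx)
  planted <- fx$truth$planted_fraction
  se <- sqrt(planted * (1 - planted) / cs$n_po_total)
  expect_lt(abs(cs$contact_fraction - planted), 3 * se + 0.02)
  expect_gte(cs$n_po_total, 55)   # nearly all planted POs detected
})

test_that("pooled one-tailed t test matches the closed form and t.test", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)

  r <- compare_groups(c(1, 2, 3), c(2, 3, 4), direction = "greater")
  expect_equal(r$t, 1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.1438, tolerance = 1e-3)
  expect_equal(r$stars, "ns")
  rev <- compare_groups(c(1, 2, 3), c(2, 3, 4), direction = "less")
  expect_equal(r$p + rev$p, 1, tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:20) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), mean = 0.5)
    ours <- compare_groups(a, b, direction = "greater")
    ref <- t.test(b, a, alternative = "greater", var.equal = TRUE)
    expect_lt(abs(ours$t - unname(ref$statistic)), 1e-10)
    expect_lt(abs(ours$p - ref$p.value), 1e-10)
    ow <- compare_groups(a, b, direction = "greater", welch = TRUE)
    rw <- t.test(b, a, alternative = "greater")
    expect_lt(abs(ow$p - rw$p.value), 1e-10)
  }
  degen <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0.5)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})
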