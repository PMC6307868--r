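# shared fixtures and independent oracles

# small imaging setup used by unit tests (fast to render)
tiny_config <- function(n_frames = 10L, shape = 256L) {
  imaging_config(n_frames = n_frames, frame_shape = c(shape, shape))
}

tiny_geometry <- function(seed = 1L, n_neurites = 3L, config = tiny_config()) {
  make_geometry(config, n_neurites = n_neurites, seed = seed,
                soma_radius = 4, neurite_length = 12)
}

# exhaustive 256-bin Otsu oracle: tries every split of the same histogram
# and maximizes the between-class variance directly
oracle_otsu <- function(values, n_bins = 256L) {
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(lo)
  bin <- pmin(pmax(floor((values - lo) / (hi - lo) * n_bins) + 1L, 1L),
              n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  best_k <- NA; best_v <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(counts[1:k] * mids[1:k]) / n0
    m1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    v <- n0 * n1 * (m0 - m1)^2
    if (v > best_v) { best_v <- v; best_k <- k }
  }
  lo + best_k * (hi - lo) / n_bins
}

# brute-force assignment oracle: enumerates every one-to-one partial
# matching obeying the gate and minimizes
# sum(matched distances) + gate * n_unmatched
oracle_assignment <- function(regions_t, regions_t1, gate) {
  n <- nrow(regions_t); m <- nrow(regions_t1)
  d <- sqrt(outer(regions_t$x_um, regions_t1$x_um, "-")^2 +
              outer(regions_t$y_um, regions_t1$y_um, "-")^2)
  best <- list(cost = Inf, matches = NULL)
  assign_next <- function(i, used, matches, cost) {
    if (i > n) {
      total <- cost + gate * ((n - nrow(matches)) + (m - nrow(matches)))
      if (total < best$cost) best <<- list(cost = total, matches = matches)
      return(invisible())
    }
    assign_next(i + 1, used, matches, cost)   # leave i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && d[i, j] <= gate) {
        used[j] <- TRUE
        assign_next(i + 1, used, rbind(matches, c(i, j)), cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  assign_next(1, rep(FALSE, m), matrix(integer(), 0, 2), 0)
  best
}

# objective value of a link_pair() assignment under the same cost model
assignment_cost <- function(asn, gate) {
  asn$total_cost + gate * (length(asn$unmatched_t) +
                             length(asn$unmatched_t1))
}

# synthetic straight Gaussian-profile ridge through the image centre at
# angle `theta` (radians; 0 = along columns), profile sigma in px
ridge_image <- function(n = 101, sigma_ridge = 2, theta = 0, amp = 100) {
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  # signed distance from the centre line with direction (sin, cos)
  d <- -(rows - ctr) * cos(theta) + (cols - ctr) * sin(theta)
  amp * exp(-d^2 / (2 * sigma_ridge^2))
}

# segmentation masks with a disk soma and one straight horizontal corridor
corridor_masks <- function(n = 120, soma_r = 15, width = 7) {
  soma_c <- c(n / 2, 25)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  soma <- (rows - soma_c[1])^2 + (cols - soma_c[2])^2 <= soma_r^2
  corridor <- abs(rows - soma_c[1]) <= (width - 1) / 2 &
    cols > soma_c[2] & cols <= n - 5
  structure(list(soma_mask = soma, neurite_mask = corridor & !soma,
                 soma_centroid = soma_c),
            class = "segmentation_masks")
}

# memoised full-pipeline cohort runs shared by the acceptance tests
.cohort_cache <- new.env(parent = emptyenv())
acceptance_cohort <- function(preset_name, seed = 7L) {
  key <- paste0(preset_name, "_", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- run_simulated_cohort(
      motility_preset(preset_name), n_neurons = 21L, n_organelles = 25L,
      config = imaging_config(), seed = seed)
  }
  .cohort_cache[[key]]
}
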