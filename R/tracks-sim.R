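#' Sample ground-truth organelle tracks
#'
#' Draws per-organelle motility classes from the preset mixture and realizes
#' each track as 1-D saltatory motion along one neurite path: a target total
#' travelled distance is sampled uniformly inside the class's distance
#' interval and decomposed into runs of constant `run_speed` (one full step
#' of `run_speed * frame_interval` per frame interval, grouped into
#' `1 + Poisson(2)` bouts with random +/- direction) plus a remainder of
#' fixed-magnitude oscillation steps, with pauses filling all other
#' intervals.  Every nonzero planted step therefore has magnitude at least
#' `oscillation_step`.  Organelles are laid out in disjoint arc-length slots
#' (1.5 um clear spacing) along the neurites so that neighbouring tracks
#' stay optically resolvable; the recorded `planted_total_distance` is the
#' realized sum of step magnitudes and always lies inside the planted
#' class's interval.
#'
#' @param geometry a [make_geometry()] result.
#' @param preset a [motility_preset()].
#' @param n_organelles number of tracks to plant (>= 1).
#' @param config an [imaging_config()].
#' @param seed integer RNG seed.
#' @param slot_gap clear arc-length spacing between neighbouring track
#'   slots, um.
#' @param soma_offset minimum arc-length distance of any slot from the soma
#'   boundary, um.
#' @return an object of class `ground_truth_tracks`: per-track planted
#'   metadata (`$summary`), per-frame positions in path and pixel
#'   coordinates (`$table`), and the generating preset/config.
#' @export
sample_tracks <- function(geometry, preset, n_organelles, config, seed = 1L,
                          slot_gap = 1.5, soma_offset = 2.5) {
  stopifnot(inherits(geometry, "neuron_geometry"),
            inherits(preset, "motility_preset"),
            inherits(config, "imaging_config"), n_organelles >= 1)
  if (length(geometry$neurite_paths) == 0)
    stop("geometry has no neurites to host tracks")
  set.seed(seed)
  dt <- config$frame_interval
  n_int <- config$n_frames - 1L
  step_run <- preset$run_speed * dt
  osc <- preset$oscillation_step
  bounds <- preset$class_distance_bounds
  is_mito <- identical(preset$organelle, "MITO")

  arcs <- lapply(seq_along(geometry$neurite_paths),
                 function(i) neurite_arclength(geometry, i))
  tracks <- vector("list", n_organelles)
  for (i in seq_len(n_organelles)) {
    cls <- sample.int(4L, 1L, prob = preset$class_probs)
    lb <- bounds[cls, 1]; ub <- bounds[cls, 2]
    target <- runif(1, lb, ub)
    n_run <- floor(target / step_run)
    n_osc <- floor((target - n_run * step_run) / osc)
    realized <- n_run * step_run + n_osc * osc
    while (realized < lb) {           # floor() can undershoot the class
      n_osc <- n_osc + 1L
      realized <- realized + osc
    }
    if (realized >= ub)
      stop("internal error: realized distance escaped its class interval")
    if (n_run + n_osc > n_int)
      stop("planted distance ", round(target, 2),
           " um unreachable in a ", n_int, "-interval session at run speed ",
           preset$run_speed, " um/s")
    steps <- .arrange_steps(n_run, n_osc, n_int, step_run, osc)
    cum <- cumsum(steps)
    m <- min(0, cum); M <- max(0, cum)
    mito_len <- if (is_mito) runif(1, 1.5, 3) else 0
    tracks[[i]] <- list(class = cls, target = target, realized = realized,
                        n_run = n_run, n_osc = n_osc, steps = steps,
                        cum = cum, excursion = c(m, M), mito_len = mito_len)
  }

  placement <- .pack_slots(tracks, arcs, slot_gap, soma_offset)

  cls_names <- motility_class_levels()
  sum_rows <- vector("list", n_organelles)
  tab_rows <- vector("list", n_organelles)
  for (i in seq_len(n_organelles)) {
    tr <- tracks[[i]]
    ni <- placement$neurite[i]
    p0 <- placement$origin[i]
    s_um <- p0 + c(0, tr$cum)
    pt <- arcs[[ni]]$point_at(s_um)
    max_speed <- if (tr$n_run > 0) preset$run_speed else
      if (tr$n_osc > 0) osc / dt else 0
    sum_rows[[i]] <- data.frame(
      track_id = i, organelle = preset$organelle, neurite_index = ni,
      planted_class = cls_names[tr$class],
      planted_total_distance = tr$realized,
      planted_max_speed = max_speed, n_run_steps = tr$n_run,
      n_osc_steps = tr$n_osc, mito_length_um = tr$mito_len)
    tab_rows[[i]] <- data.frame(
      track_id = i, organelle = preset$organelle, neurite_index = ni,
      frame = seq_len(config$n_frames), s_um = s_um,
      row = pt$row, col = pt$col,
      x_um = um_from_index(pt$col, config$pixel_size),
      y_um = um_from_index(pt$row, config$pixel_size),
      tangent_row = pt$tangent[, 1], tangent_col = pt$tangent[, 2])
  }
  structure(list(summary = do.call(rbind, sum_rows),
                 table = do.call(rbind, tab_rows),
                 preset = preset, config = config, seed = seed),
            class = "ground_truth_tracks")
}

# scatter n_run run steps (grouped into 1 + Poisson(2) signed bouts) and
# n_osc oscillation steps among n_int intervals; returns signed step vector
.arrange_steps <- function(n_run, n_osc, n_int, step_run, osc) {
  items <- list()
  if (n_run > 0) {
    k <- min(1L + rpois(1, 2), n_run)
    # random positive composition of n_run into k parts
    cuts <- sort(sample.int(n_run - 1L, k - 1L)) # empty when k == 1
    sizes <- diff(c(0L, cuts, n_run))
    for (b in sizes) items <- c(items, list(rep(sample(c(-1, 1), 1) * step_run, b)))
  }
  if (n_osc > 0)
    items <- c(items, lapply(seq_len(n_osc),
                             function(j) sample(c(-1, 1), 1) * osc))
  n_pause <- n_int - n_run - n_osc
  if (n_pause > 0) items <- c(items, lapply(seq_len(n_pause), function(j) 0))
  unlist(items[sample.int(length(items))], use.names = FALSE)
}

# assign each track a neurite and an arc-length origin so that slot
# intervals [origin + m - halo, origin + M + halo] are disjoint
.pack_slots <- function(tracks, arcs, slot_gap, soma_offset) {
  n <- length(tracks)
  widths <- vapply(tracks, function(tr)
    diff(tr$excursion) + tr$mito_len + slot_gap, numeric(1))
  usable <- vapply(arcs, function(a)
    max(0, a$length_um - soma_offset - 0.5), numeric(1))
  remaining <- usable
  neurite <- integer(n)
  # first-fit decreasing: placing wide slots first avoids fragmentation
  # failures when total capacity suffices but no single neurite has room
  order_i <- order(-widths, sample.int(n))
  for (i in order_i) {
    cand <- which(remaining >= widths[i])
    if (length(cand) == 0)
      stop("insufficient neurite capacity: a track needs ",
           round(widths[i], 1), " um of contiguous path; ", n,
           " tracks need ", round(sum(widths), 1), " um total and ",
           round(sum(usable), 1), " um are available")
    ni <- if (length(cand) == 1) cand else
      sample(cand, 1, prob = remaining[cand])
    neurite[i] <- ni
    remaining[ni] <- remaining[ni] - widths[i]
  }
  origin <- numeric(n)
  for (ni in seq_along(arcs)) {
    members <- which(neurite == ni)
    if (length(members) == 0) next
    members <- members[sample.int(length(members))]
    slack <- usable[ni] - sum(widths[members])
    k <- length(members)
    u <- sort(runif(k))
    gaps <- diff(c(0, u, 1)) * slack
    pos <- soma_offset
    for (j in seq_len(k)) {
      i <- members[j]
      pos <- pos + gaps[j]
      tr <- tracks[[i]]
      # slot occupies [pos, pos + widths[i]); origin offsets the excursion
      origin[i] <- pos - tr$excursion[1] + tr$mito_len / 2 + slot_gap / 2
      pos <- pos + widths[i]
    }
  }
  list(neurite = neurite, origin = origin)
}

#' @export
print.ground_truth_tracks <- function(x, ...) {
  tab <- table(factor(x$summary$planted_class, motility_class_levels()))
  cat(sprintf("ground_truth_tracks: %d %s track(s); classes %s\n",
              nrow(x$summary), x$preset$organelle,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
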