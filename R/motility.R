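#' Per-track motility statistics
#'
#' Computes the published per-organelle measures from one trajectory:
#' per-interval Euclidean displacements `d_i`, with steps below
#' `displacement_floor` zeroed for distance accumulation (suppressing
#' sub-resolution localization jitter); `total_distance = sum(d_i)`;
#' `net_distance` = straight-line distance between first and last centroid;
#' instantaneous speeds `d_i / frame_interval` (unfloored);
#' `max_speed = max` instantaneous speed; `avg_speed = total_distance /
#' duration` (the whole-session average, consistent with the published
#' pairing of 3.6 um travelled in a 480 s session with 0.0075 um/s).
#'
#' @param track data frame with `frame`, `x_um`, `y_um` for one track
#'   (>= 2 samples).
#' @param frame_interval seconds per frame interval.
#' @param displacement_floor um; steps below this magnitude count as 0
#'   toward total distance.
#' @return list of class `motility_summary`: `track_id`, `max_speed`,
#'   `avg_speed`, `total_distance`, `net_distance`, `motility_class`,
#'   `duration_s`, `n_samples`, `instantaneous_speeds`, `moving_fraction`
#'   (fraction of intervals at or above the floor).
#' @export
track_statistics <- function(track, frame_interval = 5,
                             displacement_floor = 0.1) {
  if (nrow(track) < 2)
    stop("track_statistics needs at least 2 samples")
  track <- track[order(track$frame), ]
  d <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  d_floored <- ifelse(d < displacement_floor, 0, d)
  total <- sum(d_floored)
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
                (track$y_um[nrow(track)] - track$y_um[1])^2)
  speeds <- d / frame_interval
  duration <- (nrow(track) - 1) * frame_interval
  structure(list(
    track_id = if ("track_id" %in% names(track)) track$track_id[1] else NA,
    max_speed = max(speeds), avg_speed = total / duration,
    total_distance = total, net_distance = net,
    motility_class = classify_motility(total),
    duration_s = duration, n_samples = nrow(track),
    instantaneous_speeds = speeds,
    moving_fraction = mean(d >= displacement_floor)),
    class = "motility_summary")
}

#' Classify a track by total travelled distance
#'
#' Four-class assignment on half-open intervals: static `[0, 1)`, very
#' short range `[1, 5)`, short range `[5, 10)`, long range `[10, Inf)` um.
#'
#' @param total_distance total travelled distance, um (>= 0).
#' @return factor with levels [motility_class_levels()].
#' @export
classify_motility <- function(total_distance) {
  if (any(total_distance < 0)) stop("total_distance must be non-negative")
  cut(total_distance, breaks = c(0, 1, 5, 10, Inf), right = FALSE,
      labels = motility_class_levels(), include.lowest = TRUE)
}

#' Summarize motility statistics for all tracks of one cohort
#'
#' @param tracks an `organelle_tracks` data frame ([build_tracks()]).
#' @param frame_interval seconds.
#' @param displacement_floor um, see [track_statistics()].
#' @param min_samples tracks with fewer samples are dropped (default 2).
#' @return data frame with one row per track (`track_id`, `organelle`,
#'   `max_speed`, `avg_speed`, `total_distance`, `net_distance`,
#'   `motility_class`, `duration_s`, `n_samples`, `moving_fraction`);
#'   attribute `speeds` pools all instantaneous speeds.
#' @export
motility_table <- function(tracks, frame_interval = 5,
                           displacement_floor = 0.1, min_samples = 2L) {
  parts <- split(seq_len(nrow(tracks)), tracks$track_id)
  rows <- list()
  speeds <- list()
  for (ix in parts) {
    if (length(ix) < min_samples) next
    s <- track_statistics(tracks[ix, , drop = FALSE], frame_interval,
                          displacement_floor)
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = s$track_id,
      organelle = if ("organelle" %in% names(tracks))
        tracks$organelle[ix[1]] else NA_character_,
      max_speed = s$max_speed, avg_speed = s$avg_speed,
      total_distance = s$total_distance, net_distance = s$net_distance,
      motility_class = as.character(s$motility_class),
      duration_s = s$duration_s, n_samples = s$n_samples,
      moving_fraction = s$moving_fraction)
    speeds[[length(speeds) + 1L]] <- s$instantaneous_speeds
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), organelle = character(),
               max_speed = numeric(), avg_speed = numeric(),
               total_distance = numeric(), net_distance = numeric(),
               motility_class = character(), duration_s = numeric(),
               n_samples = integer(), moving_fraction = numeric())
  attr(out, "speeds") <- unlist(speeds)
  attr(out, "speeds_by_track") <- setNames(speeds, out$track_id)
  out
}

#' Cohort-level motility summary
#'
#' Class fractions, mean speeds and distances, and empirical cumulative
#' distribution functions of the pooled instantaneous speeds and of the
#' per-track total distances.
#'
#' @param summaries a [motility_table()] result (>= 1 track).
#' @return list of class `cohort_summary`: `n_tracks`, `class_fractions`
#'   (named, sums to 1), `mean_avg_speed`, `mean_max_speed`,
#'   `mean_total_distance`, `ecdf_speed`, `ecdf_distance`.
#' @export
cohort_summary <- function(summaries) {
  if (nrow(summaries) == 0) stop("cohort_summary needs at least one track")
  cls <- factor(summaries$motility_class, motility_class_levels())
  fr <- as.numeric(table(cls)) / nrow(summaries)
  names(fr) <- motility_class_levels()
  speeds <- attr(summaries, "speeds")
  if (is.null(speeds)) speeds <- summaries$max_speed
  structure(list(
    n_tracks = nrow(summaries), class_fractions = fr,
    mean_avg_speed = mean(summaries$avg_speed),
    mean_max_speed = mean(summaries$max_speed),
    mean_total_distance = mean(summaries$total_distance),
    ecdf_speed = ecdf(speeds),
    ecdf_distance = ecdf(summaries$total_distance)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "cohort_summary: %d tracks | %s | avg %.4g um/s, max %.3g um/s, dist %.3g um\n",
    x$n_tracks,
    paste(names(x$class_fractions),
          sprintf("%.1f%%", 100 * x$class_fractions), collapse = " "),
    x$mean_avg_speed, x$mean_max_speed, x$mean_total_distance))
  invisible(x)
}

#' Geodesic distance to the soma within the neurite mask
#'
#' Distance (um) of every neurite-mask pixel from the soma boundary,
#' measured along 8-connected paths inside the mask (diagonal steps cost
#' `sqrt(2)` pixels).  Pixels unreachable from the soma get `Inf`; their
#' count is reported in the `unreachable` attribute.
#'
#' @param masks a `segmentation_masks` object.
#' @param pixel_size um per pixel.
#' @param seed_dilate_px how far (pixels) the soma is grown to seed the
#'   distance computation; must exceed the soma subtraction margin used in
#'   [finalize_masks()] or no neurite pixel touches the seeds.
#' @return numeric matrix (um; `Inf` outside the reachable neurite mask).
#' @export
geodesic_map <- function(masks, pixel_size = 0.08, seed_dilate_px = 14) {
  mask <- masks$neurite_mask
  dim_m <- dim(mask)
  idx <- which(mask)
  out <- matrix(Inf, dim_m[1], dim_m[2])
  if (length(idx) == 0) {
    attr(out, "unreachable") <- 0L
    return(out)
  }
  pos <- arrayInd(idx, dim_m)
  id_of <- matrix(0L, dim_m[1], dim_m[2])
  id_of[idx] <- seq_along(idx)
  edges <- list(); weights <- list()
  off <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (k in 1:4) {
    r2 <- pos[, 1] + off[k, 1]; c2 <- pos[, 2] + off[k, 2]
    ok <- r2 >= 1 & r2 <= dim_m[1] & c2 >= 1 & c2 <= dim_m[2]
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    edges[[k]] <- cbind(id_of[idx[ok]], id_of[cbind(r2[ok], c2[ok])])
    weights[[k]] <- rep(sqrt(sum(off[k, ]^2)), sum(ok))
  }
  # seed vertex connected to all neurite pixels adjacent to the soma; the
  # soma is grown past the subtraction margin of finalize_masks() so the
  # seeds actually reach the neurite mask
  soma_grown <- dilate_disc(masks$soma_mask, seed_dilate_px)
  seeds <- which(mask & soma_grown)
  nv <- length(idx) + 1L
  el <- do.call(rbind, edges)
  w <- unlist(weights)
  if (length(seeds) > 0) {
    el <- rbind(el, cbind(nv, id_of[seeds]))
    w <- c(w, rep(0.5, length(seeds)))   # half-pixel step onto the boundary
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  g <- igraph::add_edges(g, t(el), weight = w)
  d <- igraph::distances(g, v = nv)[1, seq_along(idx)]
  out[idx] <- d * pixel_size
  attr(out, "unreachable") <- sum(!is.finite(d))
  out
}

#' Directionality of a track relative to the soma
#'
#' Signed net displacement along the neurite: the change in geodesic
#' distance-to-soma between the first and last track sample; positive when
#' the organelle ends farther from the soma (anterograde), negative when it
#' ends closer (retrograde).
#'
#' @param track data frame with `frame`, `x_um`, `y_um` (or `row`/`col`).
#' @param masks a `segmentation_masks` object.
#' @param pixel_size um per pixel.
#' @param gmap optional precomputed [geodesic_map()] (saves recomputation
#'   across tracks).
#' @param snap_radius_px how far (pixels) a sample may sit from the mask
#'   and still be snapped to the nearest mask pixel.
#' @return signed net displacement along the path, um.
#' @export
directionality <- function(track, masks, pixel_size = 0.08, gmap = NULL,
                           snap_radius_px = 4) {
  if (is.null(gmap)) gmap <- geodesic_map(masks, pixel_size)
  track <- track[order(track$frame), ]
  ends <- track[c(1, nrow(track)), ]
  val <- numeric(2)
  for (i in 1:2) {
    r <- index_from_um(ends$y_um[i], pixel_size)
    c_ <- index_from_um(ends$x_um[i], pixel_size)
    val[i] <- .snap_geodesic(gmap, r, c_, snap_radius_px)
  }
  if (any(!is.finite(val)))
    stop("track endpoint lies outside the (reachable) neurite mask")
  val[2] - val[1]
}

.snap_geodesic <- function(gmap, r, c_, radius) {
  r0 <- round(r); c0 <- round(c_)
  rr <- max(1, r0 - radius):min(nrow(gmap), r0 + radius)
  cc <- max(1, c0 - radius):min(ncol(gmap), c0 + radius)
  sub <- gmap[rr, cc, drop = FALSE]
  fin <- which(is.finite(sub), arr.ind = TRUE)
  if (nrow(fin) == 0) return(Inf)
  d2 <- (rr[fin[, 1]] - r)^2 + (cc[fin[, 2]] - c_)^2
  sub[fin[which.min(d2), , drop = FALSE]]
}

#' Temporal projection of a stack
#'
#' Pixel-wise sum over all frames of one channel (the projection used to
#' visualize full trajectories and to seed kymograph line placement).
#'
#' @param frames list of frame matrices (>= 1).
#' @return numeric matrix.
#' @export
temporal_projection <- function(frames) {
  stopifnot(length(frames) >= 1)
  Reduce(`+`, lapply(frames, function(f) matrix(as.numeric(f), nrow(f))))
}

#' Generate a kymograph along a neurite line
#'
#' Samples the stack along a polyline at unit (1 px) arc steps; each
#' kymograph pixel is the maximum intensity across a `width`-pixel segment
#' perpendicular to the path, so organelles within half the line width of
#' the path are captured.  Rows are frames, columns are positions along
#' the path.
#'
#' @param frames list of frame matrices (one channel).
#' @param polyline two-column matrix of (row, col) vertices in pixels.
#' @param width odd integer >= 1, perpendicular extent in pixels.
#' @return object of class `kymograph`: `$image` (n_frames x n_path),
#'   `$polyline`, `$width`.
#' @export
make_kymograph <- function(frames, polyline, width = 5L) {
  stopifnot(length(frames) >= 1, is.matrix(polyline), ncol(polyline) == 2)
  if (width %% 2 != 1 || width < 1) stop("width must be odd and >= 1")
  shape <- dim(frames[[1]])
  if (any(polyline[, 1] < 1 | polyline[, 1] > shape[1] |
            polyline[, 2] < 1 | polyline[, 2] > shape[2]))
    stop("polyline exits the frame")
  seg <- sqrt(diff(polyline[, 1])^2 + diff(polyline[, 2])^2)
  s <- c(0, cumsum(seg))
  n_col <- max(2L, floor(s[length(s)]) + 1L)
  ss <- seq(0, s[length(s)], length.out = n_col)
  r <- approx(s, polyline[, 1], xout = ss)$y
  c_ <- approx(s, polyline[, 2], xout = ss)$y
  eps <- pmin(ss + 1, s[length(s)])
  r2 <- approx(s, polyline[, 1], xout = eps)$y
  c2 <- approx(s, polyline[, 2], xout = eps)$y
  r1 <- approx(s, polyline[, 1], xout = pmax(ss - 1, 0))$y
  c1 <- approx(s, polyline[, 2], xout = pmax(ss - 1, 0))$y
  tr <- r2 - r1; tc <- c2 - c1
  nrm <- sqrt(tr^2 + tc^2); nrm[nrm == 0] <- 1
  # unit normal
  nr_ <- -tc / nrm; nc_ <- tr / nrm
  h <- (width - 1) / 2
  offs <- -h:h
  rows_mat <- round(outer(r, rep(1, length(offs))) + outer(nr_, offs))
  cols_mat <- round(outer(c_, rep(1, length(offs))) + outer(nc_, offs))
  rows_mat <- pmin(pmax(rows_mat, 1), shape[1])
  cols_mat <- pmin(pmax(cols_mat, 1), shape[2])
  lin <- cbind(as.vector(rows_mat), as.vector(cols_mat))
  img <- matrix(0, length(frames), n_col)
  for (t in seq_along(frames)) {
    vals <- matrix(frames[[t]][lin], n_col, length(offs))
    img[t, ] <- do.call(pmax, as.data.frame(vals))
  }
  structure(list(image = img, polyline = polyline, width = width),
            class = "kymograph")
}

#' Read velocities and distances off a kymograph line
#'
#' Converts a polyline drawn on a kymograph (vertices as (row = frame,
#' col = path position) pairs, monotone in time) to physical motion:
#' per-segment velocity `|dcol| * pixel_size / (drow * frame_interval)`
#' and total distance `sum(|dcol|) * pixel_size`.
#'
#' @param vertices two-column matrix of (row, col) kymograph coordinates.
#' @param pixel_size um per pixel along the path axis.
#' @param frame_interval seconds per kymograph row.
#' @return list: `total_distance_um`, `mean_velocity_um_s`,
#'   `segment_velocities_um_s`.
#' @export
kymo_readout <- function(vertices, pixel_size = 0.08, frame_interval = 5) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 2)
  drow <- diff(vertices[, 1]); dcol <- diff(vertices[, 2])
  if (any(drow < 0)) stop("kymograph line vertices must be monotone in time")
  if (any(drow == 0)) stop("zero-duration kymograph segment")
  v <- abs(dcol) * pixel_size / (drow * frame_interval)
  total <- sum(abs(dcol)) * pixel_size
  list(total_distance_um = total,
       mean_velocity_um_s = total / (sum(drow) * frame_interval),
       segment_velocities_um_s = v)
}
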