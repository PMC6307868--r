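#' Globally optimal nearest-neighbour assignment between two frames
#'
#' Links regions detected in adjacent frames by solving the linear
#' assignment problem on centroid distances: the matching minimizes the
#' total cost `sum(matched distances) + max_link_dist * n_unmatched`, which
#' matches every pair that can be matched within the distance gate while
#' choosing the globally cheapest pairing (greedy nearest-neighbour can be
#' suboptimal for crossing organelles).  Pairs farther apart than
#' `max_link_dist` are never matched.  The solver is the Hungarian method
#' (`clue::solve_LSAP`) on a cost matrix padded with per-region "unmatched"
#' alternatives; ties are broken by region order, so linking is
#' deterministic.
#'
#' @param regions_t,regions_t1 data frames with `x_um`, `y_um` columns
#'   (regions at frames t and t+1); empty inputs give an empty assignment.
#' @param max_link_dist distance gate in um (> 0).
#' @return list of class `assignment`: `matches` (two-column matrix of row
#'   indices into the inputs), `unmatched_t`, `unmatched_t1`, `total_cost`
#'   (um, matched distances only).
#' @export
link_pair <- function(regions_t, regions_t1, max_link_dist = 1.0) {
  stopifnot(max_link_dist > 0)
  n <- if (is.null(regions_t)) 0L else nrow(regions_t)
  m <- if (is.null(regions_t1)) 0L else nrow(regions_t1)
  if (n == 0L || m == 0L) {
    return(structure(list(matches = matrix(integer(), 0, 2),
                          unmatched_t = seq_len(n),
                          unmatched_t1 = seq_len(m), total_cost = 0),
                     class = "assignment"))
  }
  d <- sqrt(outer(regions_t$x_um, regions_t1$x_um, "-")^2 +
              outer(regions_t$y_um, regions_t1$y_um, "-")^2)
  big <- (n + m) * max_link_dist * 1e3
  cost <- matrix(big, n + m, n + m)
  dd <- d
  dd[dd > max_link_dist] <- big
  cost[seq_len(n), seq_len(m)] <- dd
  for (i in seq_len(n)) cost[i, m + i] <- max_link_dist
  for (j in seq_len(m)) cost[n + j, j] <- max_link_dist
  cost[(n + 1):(n + m), (m + 1):(m + n)] <- 0
  sol <- clue::solve_LSAP(cost)
  to <- as.integer(sol)[seq_len(n)]
  matched <- which(to <= m & d[cbind(seq_len(n), pmin(to, m))] <= max_link_dist)
  matches <- cbind(t = matched, t1 = to[matched])
  structure(list(matches = matches,
                 unmatched_t = setdiff(seq_len(n), matches[, 1]),
                 unmatched_t1 = setdiff(seq_len(m), matches[, 2]),
                 total_cost = if (nrow(matches)) sum(d[matches]) else 0),
            class = "assignment")
}

#' Build trajectories from per-frame detections
#'
#' Chains [link_pair()] assignments over consecutive frames: a region
#' unmatched at frame t+1 starts a new track, a region unmatched at frame t
#' terminates its track.  There is no gap closing — tracks span strictly
#' consecutive frames.
#'
#' @param detections data frame of regions with columns `frame`, `x_um`,
#'   `y_um` (e.g. one channel of [detect_stack()] output).
#' @param max_link_dist distance gate in um per frame interval.
#' @param organelle label stored on the output tracks.
#' @return data frame of class `organelle_tracks` with columns `track_id`,
#'   `organelle`, `frame`, `x_um`, `y_um` (plus `area_um2`, `pixel_count`
#'   when present in the input), ordered by track and frame.
#' @export
build_tracks <- function(detections, max_link_dist = 1.0,
                         organelle = "PO") {
  keep_cols <- intersect(c("frame", "x_um", "y_um", "area_um2",
                           "pixel_count"), names(detections))
  det <- detections[, keep_cols, drop = FALSE]
  if (nrow(det) == 0) {
    out <- cbind(data.frame(track_id = integer(), organelle = character()),
                 det)
    class(out) <- c("organelle_tracks", class(out))
    return(out)
  }
  frames <- sort(unique(det$frame))
  by_frame <- split(seq_len(nrow(det)), det$frame)
  track_of <- integer(nrow(det))
  next_id <- 1L
  f1 <- as.character(frames[1])
  for (i in by_frame[[f1]]) {
    track_of[i] <- next_id
    next_id <- next_id + 1L
  }
  for (k in seq_len(length(frames) - 1L)) {
    ft <- frames[k]; ft1 <- frames[k + 1L]
    it <- by_frame[[as.character(ft)]]
    it1 <- by_frame[[as.character(ft1)]]
    if (ft1 != ft + 1L) {            # non-adjacent: everything is a birth
      for (i in it1) { track_of[i] <- next_id; next_id <- next_id + 1L }
      next
    }
    asn <- link_pair(det[it, , drop = FALSE], det[it1, , drop = FALSE],
                     max_link_dist)
    if (nrow(asn$matches) > 0)
      track_of[it1[asn$matches[, 2]]] <- track_of[it[asn$matches[, 1]]]
    for (j in asn$unmatched_t1) {
      track_of[it1[j]] <- next_id
      next_id <- next_id + 1L
    }
  }
  out <- cbind(data.frame(track_id = track_of, organelle = organelle), det)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("organelle_tracks", class(out))
  out
}
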