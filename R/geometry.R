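#' Generate a synthetic neuron geometry
#'
#' Plants a circular soma plus `n_neurites` smooth random-walk neurites that
#' leave the soma radially, emulating the pyramidal morphology of cultured
#' hippocampal neurons.  Each neurite is a polyline of fixed-length steps
#' whose heading performs a small random walk; every neurite is confined to
#' its own angular sector and steered away from the frame border, the soma
#' disk, and all previously laid path points, so neurites never overlap one
#' another or themselves.  Generation is deterministic for a fixed seed.
#'
#' @param config an [imaging_config()].
#' @param n_neurites number of neurites (>= 0).
#' @param seed integer RNG seed.
#' @param soma_radius soma radius, um.
#' @param neurite_width neurite width, um.
#' @param neurite_length target neurite path length, um (default 45, above
#'   the 40 um minimum the downstream analyses assume).
#' @param edge_margin clear margin to the frame border, um.
#' @return an object of class `neuron_geometry` with fields `soma_center`
#'   (matrix row/col, pixels), `soma_radius_um`, `neurite_paths` (list of
#'   two-column row/col vertex matrices; the first vertex lies on the soma
#'   boundary), `neurite_width_um` and `pixel_size`.
#' @export
make_geometry <- function(config, n_neurites = 5L, seed = 1L,
                          soma_radius = 10, neurite_width = 1.2,
                          neurite_length = 45, edge_margin = 1.5) {
  stopifnot(inherits(config, "imaging_config"), n_neurites >= 0)
  px <- config$pixel_size
  shape <- config$frame_shape
  center <- (shape + 1) / 2
  soma_r <- soma_radius / px
  r_max <- min(shape) / 2 - edge_margin / px
  len_px <- neurite_length / px
  if (n_neurites > 0 && soma_r + 12 >= r_max)
    stop("geometry infeasible: soma radius ", soma_radius,
         " um leaves no annulus inside the ", min(shape), "-px frame")
  set.seed(seed)
  geom <- structure(list(soma_center = center, soma_radius_um = soma_radius,
                         soma_radius_px = soma_r,
                         neurite_paths = list(),
                         neurite_width_um = neurite_width,
                         pixel_size = px, frame_shape = shape,
                         n_neurites = as.integer(n_neurites)),
                    class = "neuron_geometry")
  if (n_neurites == 0L) return(geom)
  if (n_neurites > 0) {
    sector_half <- (pi / n_neurites) * 0.88
    # rough area feasibility: path footprint must fit its sector annulus
    w_px <- neurite_width / px
    sector_area <- sector_half * (r_max^2 - soma_r^2)
    if (len_px * (w_px + 6) > 0.8 * sector_area)
      stop("geometry infeasible: neurite length ", neurite_length,
           " um cannot be packed into a ", round(2 * sector_half, 2),
           "-rad sector of the frame annulus")
  }
  base_angle <- runif(1, 0, 2 * pi)
  paths <- vector("list", n_neurites)
  occupied <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n_neurites)) {
    phi0 <- base_angle + 2 * pi * (i - 1) / n_neurites
    p <- NULL
    for (attempt in 1:120) {
      # relax the self-avoidance radius slightly when the walk keeps
      # getting trapped; it never drops below one neurite width
      relax <- if (attempt <= 40) 1 else if (attempt <= 80) 0.9 else 0.8
      p <- .walk_neurite(center, soma_r, r_max, phi0, sector_half, len_px,
                         avoid = occupied,
                         avoid_r = (neurite_width / px + 5) * relax)
      if (!is.null(p)) break
    }
    if (is.null(p))
      stop("geometry infeasible: could not route neurite ", i,
           " of length ", neurite_length, " um inside its sector")
    paths[[i]] <- p
    if (nrow(p) > 4) occupied <- rbind(occupied, p[seq_len(nrow(p) - 4), ])
  }
  geom$neurite_paths <- paths
  geom
}

# heading random walk with sector, annulus and self/other avoidance.
# returns NULL when trapped before reaching the target length.
.walk_neurite <- function(center, soma_r, r_max, phi0, sector_half, len_px,
                          avoid, avoid_r, step = 8) {
  n_steps <- ceiling(len_px / step)
  pts <- matrix(NA_real_, n_steps + 1, 2)
  pts[1, ] <- center + soma_r * c(sin(phi0), cos(phi0))
  theta <- phi0
  offsets <- c(0, 0.3, -0.3, 0.6, -0.6, 0.9, -0.9, 1.25, -1.25, 1.6, -1.6)
  for (s in seq_len(n_steps)) {
    theta_base <- theta + rnorm(1, 0, 0.16)
    placed <- FALSE
    for (off in offsets) {
      th <- theta_base + off
      q <- pts[s, ] + step * c(sin(th), cos(th))
      v <- q - center
      r <- sqrt(sum(v^2))
      # inner clearance ramps up over the first steps so the path can leave
      # the soma boundary, then keeps 2 um between path and soma (detected
      # soma masks are dilated before subtraction; paths hugging the soma
      # would lose their organelles to that margin)
      inner <- soma_r + min(25, 4 + 3 * s)
      if (r < inner || r > r_max) next
      dphi <- atan2(v[1], v[2]) - phi0
      dphi <- atan2(sin(dphi), cos(dphi))
      if (abs(dphi) > sector_half) next
      ok <- TRUE
      if (s > 5) {
        prev <- pts[seq_len(s - 5), , drop = FALSE]
        if (min((prev[, 1] - q[1])^2 + (prev[, 2] - q[2])^2) < avoid_r^2)
          ok <- FALSE
      }
      if (ok && nrow(avoid) > 0) {
        if (min((avoid[, 1] - q[1])^2 + (avoid[, 2] - q[2])^2) < avoid_r^2)
          ok <- FALSE
      }
      if (!ok) next
      pts[s + 1, ] <- q
      theta <- th
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  colnames(pts) <- c("row", "col")
  pts
}

#' Arc-length parameterisation of a neurite path
#'
#' @param geometry a `neuron_geometry`.
#' @param neurite_index which neurite.
#' @return list with `length_um` (total path length) and `point_at(s_um)`,
#'   a function returning interpolated `(row, col)` pixel coordinates and the
#'   unit tangent at path position `s_um` (um from the soma end).
#' @export
neurite_arclength <- function(geometry, neurite_index) {
  path <- geometry$neurite_paths[[neurite_index]]
  px <- geometry$pixel_size
  seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  s <- c(0, cumsum(seg)) * px
  total <- s[length(s)]
  point_at <- function(s_um) {
    s_um <- pmin(pmax(s_um, 0), total)
    r <- approx(s, path[, 1], xout = s_um, rule = 2)$y
    c_ <- approx(s, path[, 2], xout = s_um, rule = 2)$y
    # tangent from neighbouring samples
    eps <- min(total / 2, 0.4)
    r2 <- approx(s, path[, 1], xout = pmin(s_um + eps, total), rule = 2)$y
    c2 <- approx(s, path[, 2], xout = pmin(s_um + eps, total), rule = 2)$y
    r1 <- approx(s, path[, 1], xout = pmax(s_um - eps, 0), rule = 2)$y
    c1 <- approx(s, path[, 2], xout = pmax(s_um - eps, 0), rule = 2)$y
    tn <- cbind(r2 - r1, c2 - c1)
    nrm <- sqrt(rowSums(tn^2))
    nrm[nrm == 0] <- 1
    list(row = r, col = c_, tangent = tn / nrm)
  }
  list(length_um = total, point_at = point_at)
}

#' Rasterize geometry masks
#'
#' Builds the planted soma disk and neurite tube masks of a synthetic
#' geometry (ground truth, independent of any segmentation).
#'
#' @param geometry a `neuron_geometry`.
#' @return list of logical matrices `soma`, `neurites`, and the combined
#'   `cell` mask.
#' @export
geometry_masks <- function(geometry) {
  shape <- geometry$frame_shape
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d2 <- (rows - geometry$soma_center[1])^2 + (cols - geometry$soma_center[2])^2
  soma <- d2 <= geometry$soma_radius_px^2
  cl <- .centerline_raster(geometry)
  if (any(cl)) {
    dist_to_line <- EBImage::distmap(matrix(as.numeric(!cl), shape[1]))
    tube <- matrix(dist_to_line <= (geometry$neurite_width_um / 2) /
                     geometry$pixel_size, shape[1])
  } else {
    tube <- matrix(FALSE, shape[1], shape[2])
  }
  list(soma = soma, neurites = tube & !soma, cell = soma | tube)
}

# binary raster of all neurite centerlines
.centerline_raster <- function(geometry) {
  shape <- geometry$frame_shape
  m <- matrix(FALSE, shape[1], shape[2])
  for (path in geometry$neurite_paths) {
    seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
    s <- c(0, cumsum(seg))
    ss <- seq(0, s[length(s)], by = 0.5)
    r <- round(approx(s, path[, 1], xout = ss)$y)
    c_ <- round(approx(s, path[, 2], xout = ss)$y)
    keep <- r >= 1 & r <= shape[1] & c_ >= 1 & c_ <= shape[2]
    m[cbind(r[keep], c_[keep])] <- TRUE
  }
  m
}

#' @export
print.neuron_geometry <- function(x, ...) {
  lens <- vapply(seq_along(x$neurite_paths),
                 function(i) neurite_arclength(x, i)$length_um, numeric(1))
  cat(sprintf("neuron_geometry: soma r=%.3g um at (%.0f,%.0f), %d neurite(s)%s\n",
              x$soma_radius_um, x$soma_center[1], x$soma_center[2],
              length(x$neurite_paths),
              if (length(lens)) sprintf(", lengths %s um",
                                        paste(round(lens, 1), collapse = "/"))
              else ""))
  invisible(x)
}
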