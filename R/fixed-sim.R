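#' Render a fixed (immunostained) neuron fixture
#'
#' Plants exactly the requested numbers of peroxisome spots in the soma and
#' in the proximal 30 um of the neurites, together with a cytosol-fill
#' channel that delineates the morphology.  The spots are sub-resolution
#' objects, so their only well-defined rendered area is the binarized
#' footprint: per-spot Gaussian widths are calibrated by a short fixed-point
#' iteration so that the total footprint measured by the standard detection
#' operator (sigma = 1 px smoothing + region-restricted Otsu threshold) on a
#' noise-free render equals the requested total area per region.  Spot
#' centres respect the minimum boundary separation (centre distance
#' `>= 2 r_spot + min_spot_separation`); somatic spots are drawn from a
#' jittered hexagonal lattice (guaranteed-feasible blue-noise-like packing),
#' neurite spots are packed along the path arc length.
#'
#' @param spec a [fixed_neuron_spec()].
#' @param config an [imaging_config()]; single-frame rendering, typically
#'   1024 x 1024 px (`n_frames` is ignored; one frame is rendered).
#' @param seed integer RNG seed.
#' @param geometry optional [make_geometry()] result; generated from `seed`
#'   when `NULL`.
#' @param noise a [noise_params()].
#' @param proximal_length extent of the neurite placement region from the
#'   soma boundary, um.
#' @return an `image_stack_set` with channels `PO` and `CYTO` (one frame
#'   each); `$truth$spots` tabulates every planted spot (region, position,
#'   radius, area) and `$truth$planted` the planted totals.
#' @export
render_fixed_neuron <- function(spec, config, seed = 1L, geometry = NULL,
                                noise = noise_params(),
                                proximal_length = 30) {
  stopifnot(inherits(spec, "fixed_neuron_spec"),
            inherits(config, "imaging_config"))
  set.seed(seed)
  if (is.null(geometry))
    geometry <- make_geometry(config, n_neurites = 5L, seed = seed + 101L,
                              neurite_length = 45)
  px <- config$pixel_size
  det_sigma <- 1                      # detection smoothing the areas refer to

  spot_plan <- function(count, total_area) {
    if (count == 0) return(list(r_um = 0, sigma_px = 1, count = 0L))
    r_um <- sqrt((total_area / count) / pi)
    r_px <- r_um / px
    sigma_px <- sqrt(max((r_px / sqrt(2 * log(2)))^2 - det_sigma^2, 0.25))
    list(r_um = r_um, sigma_px = sigma_px, count = as.integer(count))
  }
  soma_plan <- spot_plan(spec$soma_po_count, spec$soma_po_area)
  neur_plan <- spot_plan(spec$neurite_po_count, spec$neurite_po_area)

  spots <- list()
  if (soma_plan$count > 0) {
    sep_px <- (2 * soma_plan$r_um + spec$min_spot_separation) / px
    pts <- .hex_disk_points(geometry$soma_center,
                            geometry$soma_radius_px - 1.5 / px,
                            spacing = sep_px + 1.7, jitter = 0.6,
                            n = soma_plan$count)
    if (is.null(pts))
      stop("infeasible packing: ", soma_plan$count,
           " spots at separation ", spec$min_spot_separation,
           " um do not fit in the soma")
    spots$soma <- data.frame(region = "soma", row = pts[, 1], col = pts[, 2],
                             r_um = soma_plan$r_um,
                             area_um2 = pi * soma_plan$r_um^2)
  }
  if (neur_plan$count > 0) {
    sep_um <- 2 * neur_plan$r_um + spec$min_spot_separation
    # keep a 1-um margin inside the proximal cutoff: a spot planted exactly
    # at the boundary can measure geodesically just past it
    pos <- .pack_path_spots(geometry, neur_plan$count, sep_um + 0.15,
                            s_min = 2, s_max = proximal_length - 1)
    if (is.null(pos))
      stop("infeasible packing: ", neur_plan$count,
           " spots do not fit in the proximal ", proximal_length,
           " um of the neurites")
    spots$neurite <- data.frame(region = "neurite", row = pos$row,
                                col = pos$col, r_um = neur_plan$r_um,
                                area_um2 = pi * neur_plan$r_um^2)
  }
  spot_tab <- if (length(spots)) do.call(rbind, spots) else
    data.frame(region = character(), row = numeric(), col = numeric(),
               r_um = numeric(), area_um2 = numeric())
  rownames(spot_tab) <- NULL

  # calibrate spot widths so the Otsu-binarized footprint on a noise-free
  # render matches the requested per-region total area (3 fixed-point steps)
  masks <- geometry_masks(geometry)
  region_mask <- list(soma = masks$soma, neurite = masks$neurites)
  sigma_of <- c(soma = soma_plan$sigma_px, neurite = neur_plan$sigma_px)
  target_area <- c(soma = spec$soma_po_area, neurite = spec$neurite_po_area)
  render_po <- function(sig_by_region) {
    po <- matrix(noise$background, config$frame_shape[1],
                 config$frame_shape[2])
    for (i in seq_len(nrow(spot_tab))) {
      p <- spot_patch(dim(po), spot_tab$row[i], spot_tab$col[i],
                      noise$spot_peak, sig_by_region[[spot_tab$region[i]]])
      if (!is.null(p)) po[p$rr, p$cc] <- po[p$rr, p$cc] + p$vals
    }
    po
  }
  if (nrow(spot_tab) > 0) {
    for (iter in 1:3) {
      po0 <- gaussian_smooth(render_po(sigma_of), det_sigma)
      for (reg in names(region_mask)) {
        if (!any(spot_tab$region == reg)) next
        m <- region_mask[[reg]]
        thr <- otsu_threshold(po0[m])
        measured <- sum(po0 > thr$threshold & m) * px^2
        if (measured > 0 && target_area[[reg]] > 0) {
          # footprint area scales ~ sigma_c^2; adjust in variance domain
          ratio <- target_area[[reg]] / measured
          s2 <- (sigma_of[[reg]]^2 + det_sigma^2) * ratio - det_sigma^2
          sigma_of[[reg]] <- sqrt(max(s2, 0.04))
        }
      }
    }
  }
  po <- render_po(sigma_of)
  cyto <- noise$background * 0.8 +
    gaussian_smooth(400 * (masks$cell + 0), 2)
  stacks <- list(PO = list(apply_noise(po, noise)),
                 CYTO = list(apply_noise(cyto, noise)))
  structure(list(stacks = stacks, config = config,
                 truth = list(spots = spot_tab, geometry = geometry,
                              spec = spec, noise = noise, seed = seed,
                              planted = list(
                                soma_count = soma_plan$count,
                                neurite_count = neur_plan$count,
                                soma_area = soma_plan$count * pi * soma_plan$r_um^2,
                                neurite_area = neur_plan$count * pi * neur_plan$r_um^2))),
            class = "image_stack_set")
}

# jittered hexagonal lattice points inside a disk; returns n sampled points
# (rows of (row, col)) or NULL when fewer than n lattice sites fit
.hex_disk_points <- function(center, radius_px, spacing, jitter, n) {
  if (radius_px <= 0) return(NULL)
  dy <- spacing * sqrt(3) / 2
  rows <- seq(-radius_px, radius_px, by = dy)
  pts <- list()
  for (k in seq_along(rows)) {
    off <- if (k %% 2 == 0) spacing / 2 else 0
    xs <- seq(-radius_px - off, radius_px, by = spacing) + off
    pts[[k]] <- cbind(rows[k], xs)
  }
  pts <- do.call(rbind, pts)
  keep <- pts[, 1]^2 + pts[, 2]^2 <= radius_px^2
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < n) return(NULL)
  ix <- sample.int(nrow(pts), n)
  sel <- pts[ix, , drop = FALSE]
  sel <- sel + matrix(runif(2 * n, -jitter, jitter), ncol = 2)
  cbind(sel[, 1] + center[1], sel[, 2] + center[2])
}

# pack n spots along the neurite paths with arc separation >= sep_um within
# [s_min, min(s_max, neurite length)]; small perpendicular jitter keeps them
# inside the tube; returns data.frame(row, col, neurite, s_um) or NULL
.pack_path_spots <- function(geometry, n, sep_um, s_min, s_max,
                             perp_jitter_px = 2.5) {
  arcs <- lapply(seq_along(geometry$neurite_paths),
                 function(i) neurite_arclength(geometry, i))
  usable <- vapply(arcs, function(a)
    max(0, min(s_max, a$length_um - 0.5) - s_min), numeric(1))
  cap <- pmax(0, floor(usable / sep_um))
  if (sum(cap) < n) return(NULL)
  # allocate counts proportional to capacity
  alloc <- floor(cap * n / sum(cap))
  while (sum(alloc) < n) {
    i <- which.max(cap - alloc)
    alloc[i] <- alloc[i] + 1L
  }
  if (any(alloc > cap)) {
    over <- which(alloc > cap)
    for (i in over) {
      extra <- alloc[i] - cap[i]
      alloc[i] <- cap[i]
      room <- which(alloc < cap)
      for (j in head(room, extra)) alloc[j] <- alloc[j] + 1L
    }
  }
  if (sum(alloc) < n) return(NULL)
  out <- list()
  for (i in seq_along(arcs)) {
    k <- alloc[i]
    if (k == 0) next
    slack <- usable[i] - k * sep_um
    u <- sort(runif(k))
    gaps <- diff(c(0, u, 1)) * slack
    s <- s_min + cumsum(gaps[seq_len(k)] + sep_um) - sep_um / 2
    pt <- arcs[[i]]$point_at(s)
    # perpendicular jitter
    off <- runif(k, -perp_jitter_px, perp_jitter_px)
    out[[i]] <- data.frame(row = pt$row + off * pt$tangent[, 2],
                           col = pt$col - off * pt$tangent[, 1],
                           neurite = i, s_um = s)
  }
  do.call(rbind, out)
}
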