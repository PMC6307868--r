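#' Rendering noise and intensity parameters
#'
#' Camera/photon model used by the simulator: a Poisson draw on the expected
#' photon count followed by additive Gaussian read noise, quantized to
#' integer counts.  Defaults give sub-0.1-px centroid noise on organelle
#' spots so that downstream recovery is detection-limited rather than
#' noise-limited: uniform background 100 counts, neurite cytoplasm +60,
#' soma +150, peroxisome spot peak 900, mitochondria peak 600, read noise
#' sigma 10.
#'
#' @param background uniform background level, counts.
#' @param neurite_boost additional counts inside the neurite tube.
#' @param soma_boost additional counts inside the soma disk.
#' @param spot_peak peroxisome spot peak amplitude, counts.
#' @param mito_peak mitochondria capsule peak amplitude, counts.
#' @param read_sigma Gaussian read noise standard deviation, counts.
#' @param poisson logical; apply Poisson photon noise.
#' @param spot_sigma_um peroxisome spot Gaussian sigma, um (diffraction-like).
#' @return a list of class `noise_params`.
#' @export
noise_params <- function(background = 100, neurite_boost = 60,
                         soma_boost = 150, spot_peak = 900, mito_peak = 600,
                         read_sigma = 10, poisson = TRUE,
                         spot_sigma_um = 0.15) {
  structure(as.list(environment()), class = "noise_params")
}

# static background image (counts, noise-free) for a geometry
render_background <- function(geometry, noise = noise_params()) {
  masks <- geometry_masks(geometry)
  base <- matrix(noise$background, geometry$frame_shape[1],
                 geometry$frame_shape[2])
  boost <- noise$neurite_boost * (masks$neurites | masks$soma) +
    noise$soma_boost * masks$soma
  base + gaussian_smooth(boost, 2)
}

# Gaussian spot patch at continuous (row, col); returns list(rr, cc, vals)
# so callers can accumulate into a frame without copy-on-modify churn
spot_patch <- function(shape, row, col, amp, sigma_px, half = NULL) {
  if (is.null(half)) half <- ceiling(3 * sigma_px) + 1L
  r0 <- round(row); c0 <- round(col)
  rr <- max(1L, r0 - half):min(shape[1], r0 + half)
  cc <- max(1L, c0 - half):min(shape[2], c0 + half)
  if (length(rr) == 0 || length(cc) == 0) return(NULL)
  list(rr = rr, cc = cc,
       vals = amp * outer(exp(-(rr - row)^2 / (2 * sigma_px^2)),
                          exp(-(cc - col)^2 / (2 * sigma_px^2))))
}

# add a 2-D Gaussian spot at continuous (row, col) into frame
stamp_spot <- function(frame, row, col, amp, sigma_px, half = NULL) {
  p <- spot_patch(dim(frame), row, col, amp, sigma_px, half)
  if (is.null(p)) return(frame)
  frame[p$rr, p$cc] <- frame[p$rr, p$cc] + p$vals
  frame
}

# soft-edged capsule patch centred at (row, col) with unit tangent
# (trow, tcol), half length h_px, core radius and edge sigma
capsule_patch <- function(shape, row, col, trow, tcol, amp, h_px,
                          core_px = 2, edge_px = 1.5) {
  half <- ceiling(h_px + core_px + 3 * edge_px)
  r0 <- round(row); c0 <- round(col)
  rr <- max(1L, r0 - half):min(shape[1], r0 + half)
  cc <- max(1L, c0 - half):min(shape[2], c0 + half)
  if (length(rr) == 0 || length(cc) == 0) return(NULL)
  dr <- outer(rr - row, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - col)
  along <- dr * trow + dc * tcol
  along_clamped <- pmin(pmax(along, -h_px), h_px)
  d <- sqrt((dr - along_clamped * trow)^2 + (dc - along_clamped * tcol)^2)
  excess <- pmax(d - core_px, 0)
  list(rr = rr, cc = cc, vals = amp * exp(-excess^2 / (2 * edge_px^2)))
}

# add a capsule into frame
stamp_capsule <- function(frame, row, col, trow, tcol, amp, h_px,
                          core_px = 2, edge_px = 1.5) {
  p <- capsule_patch(dim(frame), row, col, trow, tcol, amp, h_px, core_px,
                     edge_px)
  if (is.null(p)) return(frame)
  frame[p$rr, p$cc] <- frame[p$rr, p$cc] + p$vals
  frame
}

# apply Poisson photon noise + Gaussian read noise, quantize to counts
apply_noise <- function(frame, noise) {
  n <- length(frame)
  out <- if (isTRUE(noise$poisson))
    rpois(n, pmax(frame, 0)) else round(frame)
  if (noise$read_sigma > 0)
    out <- out + round(rnorm(n, 0, noise$read_sigma))
  matrix(as.integer(pmax(out, 0)), nrow(frame), ncol(frame))
}

#' Render a two-channel time-lapse stack from planted tracks
#'
#' Produces the simulated acquisition: peroxisomes as diffraction-limited
#' 2-D Gaussian spots and mitochondria as soft-edged elongated capsules
#' moving along the planted trajectories on a dim neurite-shaped background
#' (bright enough for ridge tracing), with Poisson photon noise and Gaussian
#' read noise.  Bit-identical output for a fixed seed.
#'
#' @param geometry a [make_geometry()] result.
#' @param po_tracks,mito_tracks [sample_tracks()] results (either may be
#'   `NULL`); channels without tracks are not rendered.
#' @param config an [imaging_config()].
#' @param noise a [noise_params()].
#' @param seed integer RNG seed for the noise draws.
#' @return an object of class `image_stack_set`: `$stacks` is a named list
#'   of channels, each a list of integer frame matrices; `$truth` holds the
#'   planted ground truth (tracks, geometry, preset parameters).
#' @export
render_timelapse <- function(geometry, po_tracks = NULL, mito_tracks = NULL,
                             config, noise = noise_params(), seed = 1L) {
  stopifnot(inherits(config, "imaging_config"))
  for (gt in list(po_tracks, mito_tracks)) {
    if (!is.null(gt)) {
      pos <- gt$table
      if (any(pos$row < 1 | pos$row > config$frame_shape[1] |
                pos$col < 1 | pos$col > config$frame_shape[2]))
        stop("planted tracks leave the frame; enlarge frame_shape or ",
             "shorten neurites")
    }
  }
  set.seed(seed)
  bg <- render_background(geometry, noise)
  sigma_px <- noise$spot_sigma_um / config$pixel_size
  stacks <- list()
  channels <- list(PO = po_tracks, MITO = mito_tracks)
  for (ch in names(channels)) {
    gt <- channels[[ch]]
    if (is.null(gt)) next
    tab <- gt$table
    by_frame <- split(seq_len(nrow(tab)), tab$frame)
    mito_half <- (gt$summary$mito_length_um / 2) / config$pixel_size
    shape <- config$frame_shape
    frames <- vector("list", config$n_frames)
    for (t in seq_len(config$n_frames)) {
      fr <- bg + 0                  # fresh copy; patches add in place below
      ix <- by_frame[[as.character(t)]]
      for (j in ix) {
        p <- if (ch == "PO")
          spot_patch(shape, tab$row[j], tab$col[j], noise$spot_peak,
                     sigma_px)
        else
          capsule_patch(shape, tab$row[j], tab$col[j], tab$tangent_row[j],
                        tab$tangent_col[j], noise$mito_peak,
                        mito_half[tab$track_id[j]])
        if (!is.null(p)) fr[p$rr, p$cc] <- fr[p$rr, p$cc] + p$vals
      }
      frames[[t]] <- apply_noise(fr, noise)
    }
    stacks[[ch]] <- frames
  }
  structure(list(stacks = stacks, config = config,
                 truth = list(po = po_tracks, mito = mito_tracks,
                              geometry = geometry, noise = noise,
                              seed = seed)),
            class = "image_stack_set")
}

#' @export
print.image_stack_set <- function(x, ...) {
  cat(sprintf("image_stack_set: channels [%s], %d frame(s) of %dx%d px\n",
              paste(names(x$stacks), collapse = ", "),
              length(x$stacks[[1]]), nrow(x$stacks[[1]][[1]]),
              ncol(x$stacks[[1]][[1]])))
  invisible(x)
}
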