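#' Frangi filter parameters
#'
#' @param scales Gaussian scales (sigma, pixels) of the multi-scale Hessian;
#'   non-empty, positive.
#' @param beta blobness weight of the vesselness measure.
#' @param gamma structureness weight; `NULL` (default) uses half the maximum
#'   sigma-normalized Hessian norm of the image at each scale.
#' @return a list of class `frangi_params`.
#' @export
frangi_params <- function(scales = c(1, 2, 3, 4), beta = 0.5, gamma = NULL) {
  stopifnot(length(scales) >= 1, all(scales > 0), beta > 0)
  structure(list(scales = scales, beta = beta, gamma = gamma),
            class = "frangi_params")
}

# sigma^2-normalized Gaussian-derivative Hessian of a 2-D image.
# x = column direction, y = row direction.
hessian_gaussian <- function(image, sigma) {
  h <- max(2L, ceiling(3.5 * sigma))
  t <- -h:h
  g <- dnorm(t, sd = sigma); g <- g / sum(g)
  g1 <- -(t / sigma^2) * g
  g2 <- ((t^2 - sigma^2) / sigma^4) * g
  g2 <- g2 - mean(g2)             # zero DC: constant images give 0 exactly
  s2 <- sigma^2
  list(xx = s2 * sep_filter(image, g, g2),
       yy = s2 * sep_filter(image, g2, g),
       xy = s2 * sep_filter(image, g1, g1))
}

#' Multi-scale Frangi ridge response
#'
#' Computes the bright-ridge vesselness of the sigma-normalized Hessian at
#' each scale and keeps the per-pixel maximum over scales.  With Hessian
#' eigenvalues `|l1| <= |l2|`, the response is zero where `l2 >= 0` (no
#' bright ridge) and otherwise
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with blobness
#' `Rb = l1/l2` and structureness `S = sqrt(l1^2 + l2^2)`; `c` defaults to
#' half the maximum `S` at that scale.  The ridge orientation (direction
#' along the ridge, i.e. the minor-eigenvector direction) is recorded at
#' the scale achieving the maximum.
#'
#' @param image 2-D numeric matrix with finite values.
#' @param params a [frangi_params()].
#' @return an object of class `ridge_map`: `$strength` (>= 0),
#'   `$orientation` (radians, along-ridge, in `[0, pi)`), `$scales_used`.
#' @export
frangi_response <- function(image, params = frangi_params()) {
  if (!is.matrix(image) || length(image) == 0)
    stop("frangi_response needs a non-empty 2-D image")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  best <- matrix(0, nrow(image), ncol(image))
  orient <- matrix(0, nrow(image), ncol(image))
  for (sigma in params$scales) {
    H <- hessian_gaussian(image, sigma)
    half_tr <- (H$xx + H$yy) / 2
    root <- sqrt(((H$xx - H$yy) / 2)^2 + H$xy^2)
    e1 <- half_tr + root                      # algebraically larger
    e2 <- half_tr - root
    swap <- abs(e1) > abs(e2)                 # enforce |l1| <= |l2|
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    c2 <- if (is.null(params$gamma)) max(S2) / 4 else params$gamma^2
    v <- matrix(0, nrow(image), ncol(image))
    # absolute tolerance: rounding residue of the zero-DC kernels on flat
    # images must not register as curvature (the per-image normalization
    # would otherwise amplify it to order-one responses)
    tol <- 1e-9 * max(abs(image))
    ridge <- l2 < -tol
    if (any(ridge) && c2 > 0) {
      rb2 <- (l1[ridge] / l2[ridge])^2
      v[ridge] <- exp(-rb2 / (2 * params$beta^2)) *
        (1 - exp(-S2[ridge] / (2 * c2)))
    }
    upd <- v > best
    if (any(upd)) {
      # normal = eigenvector of l2; ridge direction is its perpendicular
      vx <- H$xy[upd]
      vy <- l2[upd] - H$xx[upd]
      degen <- abs(vx) + abs(vy) < 1e-12
      vx[degen] <- 1; vy[degen] <- 0
      ang <- atan2(vx, -vy)                   # perpendicular of (vx, vy)
      orient[upd] <- ang %% pi
      best[upd] <- v[upd]
    }
  }
  structure(list(strength = best, orientation = orient,
                 scales_used = params$scales), class = "ridge_map")
}

# Canny-style non-maximal suppression across the ridge: keep pixels that are
# maximal along the normal (across-ridge) direction, quantized to 4 axes
nonmax_suppress <- function(strength, orientation) {
  nr <- nrow(strength); nc <- ncol(strength)
  normal <- (orientation + pi / 2) %% pi
  bin <- as.integer(floor(((normal + pi / 8) %% pi) / (pi / 4))) %% 4L
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- strength
  shift <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  # bins: 0 = normal along x (cols), 1 = diagonal (dr,dc)=(1,1),
  # 2 = normal along y (rows), 3 = anti-diagonal (1,-1)
  n1 <- list(shift(0, 1), shift(1, 1), shift(1, 0), shift(1, -1))
  n2 <- list(shift(0, -1), shift(-1, -1), shift(-1, 0), shift(-1, 1))
  keep <- matrix(FALSE, nr, nc)
  for (b in 0:3) {
    sel <- bin == b
    keep[sel] <- strength[sel] >= n1[[b + 1]][sel] &
      strength[sel] >= n2[[b + 1]][sel]
  }
  out <- strength
  out[!keep] <- 0
  out
}

#' Trace neurites by hysteresis thresholding of a ridge map
#'
#' Thins the ridge strength by non-maximal suppression across the local
#' ridge orientation, then applies double-threshold hysteresis: pixels with
#' thinned strength `>= high` seed the trace and pixels `>= low` are kept
#' iff 8-connected to a seed through pixels `>= low` (the ridge analogue of
#' Canny edge tracking).  The thinned trace is finally dilated to the
#' physical neurite width to form an analysis mask with area.
#'
#' @param ridge a [frangi_response()] result.
#' @param low,high hysteresis thresholds (`0 <= low <= high`).  By default
#'   `high` is the Otsu threshold of the nonzero thinned strengths computed
#'   on a log10 intensity axis (vesselness spans several decades — a noise
#'   floor, a dim-cytoplasm tube mode and bright organelle-trail ridges —
#'   and a linear-domain histogram split lands between the two bright modes
#'   instead of above the noise), and `low = 0.5 * high`.
#' @param neurite_width_um,pixel_size physical dilation of the thinned
#'   trace; `dilate_radius_px = round(neurite_width_um / 2 / pixel_size)`.
#'   Set `neurite_width_um = 0` to return the 1-px trace.
#' @return logical neurite-candidate mask with attributes `low`, `high` and
#'   `thinned` (the suppressed strength map).
#' @export
trace_neurites <- function(ridge, low = NULL, high = NULL,
                           neurite_width_um = 1.2, pixel_size = 0.08) {
  stopifnot(inherits(ridge, "ridge_map"))
  thinned <- nonmax_suppress(ridge$strength, ridge$orientation)
  nz <- thinned[thinned > 0]
  if (is.null(high))
    high <- if (length(nz) >= 2)
      10^otsu_threshold(log10(nz))$threshold else Inf
  if (is.null(low)) low <- 0.5 * high
  if (low > high) stop("hysteresis thresholds must satisfy low <= high")
  if (low < 0) stop("hysteresis thresholds must be non-negative")
  cand <- thinned >= low & thinned > 0
  keep <- matrix(FALSE, nrow(cand), ncol(cand))
  if (any(cand) && is.finite(high)) {
    lab <- label_components8(cand)
    n <- max(lab)
    if (n > 0) {
      seed_labels <- unique(lab[thinned >= high & lab > 0])
      keep <- matrix(lab %in% seed_labels & lab > 0, nrow(cand))
    }
  }
  r <- round(neurite_width_um / 2 / pixel_size)
  mask <- if (r > 0) dilate_disc(keep, r) else keep
  attr(mask, "low") <- low
  attr(mask, "high") <- high
  attr(mask, "thinned") <- thinned
  attr(mask, "trace") <- keep
  mask
}

#' Detect the soma with a scale-space difference-of-Gaussian filter
#'
#' The image is band-pass filtered at several scales (each response is the
#' difference between blurs at `sigma` and `1.6 sigma`), the per-pixel
#' maximum response is thresholded with Otsu's method, and the largest
#' 8-connected component — with interior holes filled — is returned as the
#' soma mask.  Filtering runs on a block-averaged image (factor
#' `downsample`) since the soma is two orders of magnitude larger than a
#' pixel, and on log-compressed intensities: fluorescence spans decades,
#' and on a linear scale the band-pass response of bright organelle trails
#' (mitochondria especially) can dominate the dimmer soma body.
#'
#' @param image 2-D numeric matrix (typically the temporal projection).
#' @param scales_px DoG scales (sigma, pixels, at full resolution); the
#'   defaults 10-40 px give sensitivity to blob radii of roughly 1-4.5 um at
#'   0.08 um/px.
#' @param downsample integer block-averaging factor (>= 1).
#' @param opening_px radius (full-resolution pixels) of a morphological
#'   opening applied to the thresholded response before picking the largest
#'   component.  The DoG of bright organelle trails along neurites responds
#'   too; without the opening those bands (which spread roughly one filter
#'   scale beyond the trail) can stay 8-connected to the soma response and
#'   the "largest object" grows tentacles along the neurites.  The default
#'   exceeds the widest trail band while staying far below the soma
#'   diameter.  Set to 0 to disable.
#' @param compress `"log"` (default) filters `log1p(image - min(image))`;
#'   `"none"` filters raw intensities.
#' @return logical soma mask.  Fails with a condition of class
#'   `neuromot_no_soma` when no component survives thresholding.
#' @export
detect_soma <- function(image, scales_px = c(10, 15, 20, 25, 30, 40),
                        downsample = 4L, opening_px = 64,
                        compress = c("log", "none")) {
  stopifnot(is.matrix(image), length(image) > 0)
  compress <- match.arg(compress)
  if (compress == "log") image <- log1p(image - min(image))
  f <- max(1L, as.integer(downsample))
  small <- downsample_mean(image, f)
  resp <- matrix(-Inf, nrow(small), ncol(small))
  for (s in scales_px / f) {
    b1 <- gaussian_smooth(small, s)
    b2 <- gaussian_smooth(small, 1.6 * s)
    resp <- pmax(resp, b1 - b2)
  }
  vals <- as.vector(resp)
  if (length(unique(vals)) < 2)
    stop(.no_soma_condition("constant DoG response; no soma-like object"))
  thr <- otsu_threshold(vals)
  if (thr$degenerate)
    stop(.no_soma_condition("degenerate DoG response histogram"))
  bin <- resp > thr$threshold
  if (!any(bin))
    stop(.no_soma_condition("no pixels above the DoG threshold"))
  re <- round(opening_px / f)
  if (re > 0) {
    er <- EBImage::erode(matrix(as.numeric(bin), nrow(bin)),
                         EBImage::makeBrush(2L * re + 1L, "disc")) > 0
    if (!any(er))
      stop(.no_soma_condition("no component survives the opening"))
    comp <- dilate_disc(largest_component(er), re)
  } else {
    comp <- largest_component(bin)
  }
  comp <- EBImage::fillHull(matrix(as.numeric(comp), nrow(comp))) > 0
  mask <- upsample_nn(comp, f, dim(image))
  if (!any(mask)) stop(.no_soma_condition("empty soma component"))
  mask
}

.no_soma_condition <- function(msg) {
  structure(class = c("neuromot_no_soma", "error", "condition"),
            list(message = paste0("NoSomaFound: ", msg), call = NULL))
}

#' Combine neurite candidates and soma into final segmentation masks
#'
#' The soma (dilated by `soma_margin_px` to suppress halo detections at its
#' boundary) is subtracted from the neurite-candidate mask, so no pixel is
#' ever assigned to both compartments.
#'
#' @param neurite_candidates logical mask from [trace_neurites()].
#' @param soma_mask logical mask from [detect_soma()].
#' @param soma_margin_px dilation radius applied to the soma before
#'   subtraction.
#' @return an object of class `segmentation_masks` with fields `soma_mask`,
#'   `neurite_mask` and `soma_centroid` (row/col pixel coordinates).
#' @export
finalize_masks <- function(neurite_candidates, soma_mask,
                           soma_margin_px = 12L) {
  stopifnot(all(dim(neurite_candidates) == dim(soma_mask)))
  soma <- soma_mask != 0
  grown <- dilate_disc(soma, soma_margin_px)
  neurite <- (neurite_candidates != 0) & !grown
  centroid <- if (any(soma)) {
    ix <- which(soma, arr.ind = TRUE)
    colMeans(ix)
  } else c(NA_real_, NA_real_)
  structure(list(soma_mask = soma, neurite_mask = neurite,
                 soma_centroid = centroid),
            class = "segmentation_masks")
}

#' Segment a neuron from a rendered or recorded stack set
#'
#' Builds the segmentation input as the sum of the per-channel temporal
#' maximum projections (symmetrizing channel brightness), traces neurites
#' with [frangi_response()] + [trace_neurites()], detects the soma with
#' [detect_soma()], and combines both with [finalize_masks()].
#'
#' @param stack_set an `image_stack_set`.
#' @param frangi a [frangi_params()].
#' @param neurite_width_um physical neurite width for mask dilation.
#' @param scales_px DoG soma scales, see [detect_soma()].
#' @param soma_margin_px see [finalize_masks()].
#' @param presmooth_sigma Gaussian pre-smoothing (pixels) of the projection
#'   before ridge filtering; suppresses per-pixel shot noise (which
#'   otherwise seeds percolating spurious ridges) while leaving the much
#'   wider neurite tube intact.  0 disables.
#' @return a `segmentation_masks` object.
#' @export
segment_neuron <- function(stack_set, frangi = frangi_params(),
                           neurite_width_um = 1.2,
                           scales_px = c(10, 15, 20, 25, 30, 40),
                           soma_margin_px = 12L, presmooth_sigma = 2) {
  stopifnot(inherits(stack_set, "image_stack_set"))
  proj <- NULL
  for (ch in names(stack_set$stacks)) {
    mx <- Reduce(pmax, stack_set$stacks[[ch]])
    proj <- if (is.null(proj)) mx else proj + mx
  }
  proj <- matrix(as.numeric(proj), nrow(proj))
  ridge_input <- if (presmooth_sigma > 0)
    gaussian_smooth(proj, presmooth_sigma) else proj
  ridge <- frangi_response(ridge_input, frangi)
  cand <- trace_neurites(ridge, neurite_width_um = neurite_width_um,
                         pixel_size = stack_set$config$pixel_size)
  soma <- detect_soma(proj, scales_px = scales_px)
  finalize_masks(cand, soma, soma_margin_px = soma_margin_px)
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat(sprintf("segmentation_masks: soma %d px (centroid %.0f,%.0f), neurites %d px\n",
              sum(x$soma_mask), x$soma_centroid[1], x$soma_centroid[2],
              sum(x$neurite_mask)))
  invisible(x)
}
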