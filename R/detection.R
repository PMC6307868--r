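#' Otsu threshold of a value sample
#'
#' Histogram threshold maximizing the between-class variance over a 256-bin
#' histogram of the provided values only (typically the smoothed pixel
#' values inside the neurite mask).  Values strictly greater than the
#' returned threshold belong to the foreground class.
#'
#' @param values numeric vector (>= 2 values).
#' @param n_bins histogram resolution.
#' @return list with `threshold` and logical `degenerate` (`TRUE` when all
#'   values are identical, in which case `threshold` equals that value).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("otsu_threshold needs at least 2 values")
  lo <- min(values); hi <- max(values)
  if (hi <= lo) return(list(threshold = lo, degenerate = TRUE))
  bin <- pmin(pmax(floor((values - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  n <- length(values)
  w0 <- cumsum(counts) / n
  m0 <- cumsum(counts * mids)
  mt <- m0[n_bins]
  valid <- w0 > 0 & w0 < 1
  sb2 <- rep(-Inf, n_bins)
  sb2[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(sb2)
  list(threshold = lo + k * (hi - lo) / n_bins, degenerate = FALSE)
}

#' Organelle detection parameters
#'
#' @param sigma Gaussian smoothing sigma in pixels: 1 for the compact
#'   peroxisome spots, 2 for the larger mitochondria.
#' @param min_size minimum component size in pixels (single-pixel noise
#'   filter).
#' @param connectivity pixel connectivity (8 only).
#' @return list of class `detection_params`.
#' @export
detection_params <- function(sigma = 1, min_size = 4L, connectivity = 8L) {
  stopifnot(sigma > 0, min_size >= 1, connectivity == 8L)
  structure(list(sigma = sigma, min_size = as.integer(min_size),
                 connectivity = 8L), class = "detection_params")
}

#' Detect organelle regions in one frame
#'
#' Smooths the frame, computes the Otsu threshold from the smoothed values
#' at mask pixels only, binarizes within the mask, and returns 8-connected
#' components of at least `min_size` pixels with intensity-weighted
#' centroids in physical units.
#'
#' @param frame numeric matrix.
#' @param mask logical matrix (same shape, non-empty).
#' @param params a [detection_params()].
#' @param pixel_size um per pixel.
#' @param frame_index frame number recorded in the output.
#' @param threshold optional externally supplied threshold (used by
#'   [detect_stack()] to carry a threshold over degenerate frames);
#'   `NULL` computes Otsu.
#' @return data frame with one row per region: `frame`, `label`, `row`,
#'   `col` (continuous pixel coordinates), `x_um`, `y_um`, `pixel_count`,
#'   `area_um2`, bounding box columns; attributes `labels` (label image),
#'   `threshold`, `degenerate`.
#' @export
detect_regions <- function(frame, mask, params = detection_params(),
                           pixel_size = 0.08, frame_index = 1L,
                           threshold = NULL) {
  if (!all(dim(frame) == dim(mask)))
    stop("frame and mask shapes differ")
  if (!any(mask)) stop("mask is empty: no region to threshold ",
                       "(this is distinct from finding no detections)")
  smooth <- gaussian_smooth(matrix(as.numeric(frame), nrow(frame)),
                            params$sigma)
  degenerate <- FALSE
  if (is.null(threshold)) {
    ot <- otsu_threshold(smooth[mask])
    threshold <- ot$threshold
    degenerate <- ot$degenerate
  }
  bin <- smooth > threshold & mask
  lab <- label_components8(bin)
  empty <- data.frame(frame = integer(), label = integer(), row = numeric(),
                      col = numeric(), x_um = numeric(), y_um = numeric(),
                      pixel_count = integer(), area_um2 = numeric(),
                      bbox_rmin = integer(), bbox_rmax = integer(),
                      bbox_cmin = integer(), bbox_cmax = integer())
  n <- max(lab)
  if (n == 0L) {
    out <- empty
  } else {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(sizes >= params$min_size)
    if (length(keep) == 0L) {
      out <- empty
    } else {
      idx <- which(lab > 0L)
      l <- lab[idx]
      sel <- l %in% keep
      idx <- idx[sel]; l <- l[sel]
      rc <- arrayInd(idx, dim(frame))
      w <- smooth[idx]
      lf <- factor(l, levels = keep)
      sw <- rowsum(w, lf)[, 1]
      r <- rowsum(w * rc[, 1], lf)[, 1] / sw
      c_ <- rowsum(w * rc[, 2], lf)[, 1] / sw
      out <- data.frame(
        frame = as.integer(frame_index), label = keep, row = r, col = c_,
        x_um = um_from_index(c_, pixel_size),
        y_um = um_from_index(r, pixel_size),
        pixel_count = sizes[keep],
        area_um2 = sizes[keep] * pixel_size^2,
        bbox_rmin = as.integer(tapply(rc[, 1], lf, min)),
        bbox_rmax = as.integer(tapply(rc[, 1], lf, max)),
        bbox_cmin = as.integer(tapply(rc[, 2], lf, min)),
        bbox_cmax = as.integer(tapply(rc[, 2], lf, max)))
      rownames(out) <- NULL
    }
  }
  attr(out, "labels") <- lab
  attr(out, "threshold") <- threshold
  attr(out, "degenerate") <- degenerate
  out
}

#' Detect organelles across a stack
#'
#' Applies [detect_regions()] to every frame of the requested channels,
#' restricted to the neurite mask.  The Otsu threshold is recomputed per
#' frame (adapting to bleaching); a frame with a degenerate histogram
#' inherits the previous frame's threshold.
#'
#' @param stack_set an `image_stack_set`.
#' @param masks a `segmentation_masks` object.
#' @param params named list of [detection_params()] per channel (defaults:
#'   sigma 1 for `PO`, 2 for `MITO`).
#' @param channels channels to process (default: all rendered).
#' @return data frame of regions with a `channel` column; attribute
#'   `degenerate_frames` names frames that inherited a threshold.
#' @export
detect_stack <- function(stack_set, masks,
                         params = list(PO = detection_params(sigma = 1),
                                       MITO = detection_params(sigma = 2)),
                         channels = NULL) {
  stopifnot(inherits(stack_set, "image_stack_set"),
            inherits(masks, "segmentation_masks"))
  if (is.null(channels)) channels <- names(stack_set$stacks)
  out <- list()
  degen <- character()
  for (ch in channels) {
    frames <- stack_set$stacks[[ch]]
    if (is.null(frames)) stop("channel not present in stack: ", ch)
    p <- params[[ch]]
    if (is.null(p)) p <- detection_params()
    prev_thr <- NULL
    for (t in seq_along(frames)) {
      reg <- detect_regions(frames[[t]], masks$neurite_mask, p,
                            pixel_size = stack_set$config$pixel_size,
                            frame_index = t)
      if (attr(reg, "degenerate") && !is.null(prev_thr)) {
        reg <- detect_regions(frames[[t]], masks$neurite_mask, p,
                              pixel_size = stack_set$config$pixel_size,
                              frame_index = t, threshold = prev_thr)
        degen <- c(degen, paste0(ch, ":", t))
      } else {
        prev_thr <- attr(reg, "threshold")
      }
      if (nrow(reg) > 0) {
        reg$channel <- ch
        out[[length(out) + 1L]] <- reg
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    r <- detect_regions(matrix(0, 2, 2) + 0, matrix(TRUE, 2, 2))
    r$channel <- character(0)
    r[0, ]
  }
  rownames(res) <- NULL
  attr(res, "degenerate_frames") <- degen
  res
}
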