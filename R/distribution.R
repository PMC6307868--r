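#' Partition the neuron into soma and proximal-neurite regions
#'
#' The proximal region is the set of neurite-mask pixels within a geodesic
#' distance `length` (default 30 um) of the soma boundary, measured inside
#' the neurite mask.  Neurite pixels unreachable from the soma are excluded
#' and counted in the `unreachable_px` diagnostic.
#'
#' @param masks a `segmentation_masks` object (non-empty soma and neurite
#'   masks).
#' @param length proximal extent, um.
#' @param pixel_size um per pixel.
#' @return object of class `region_partition`: `soma` and `proximal`
#'   logical masks (always disjoint), `soma_area_um2`, `proximal_area_um2`,
#'   `unreachable_px`.
#' @export
proximal_region <- function(masks, length = 30, pixel_size = 0.08) {
  stopifnot(inherits(masks, "segmentation_masks"))
  if (!any(masks$soma_mask)) stop("empty soma mask")
  if (!any(masks$neurite_mask)) stop("empty neurite mask")
  gmap <- geodesic_map(masks, pixel_size)
  prox <- is.finite(gmap) & gmap <= length
  structure(list(
    soma = masks$soma_mask, proximal = prox & !masks$soma_mask,
    soma_area_um2 = sum(masks$soma_mask) * pixel_size^2,
    proximal_area_um2 = sum(prox & !masks$soma_mask) * pixel_size^2,
    unreachable_px = attr(gmap, "unreachable")),
    class = "region_partition")
}

#' Peroxisome distribution between soma and proximal neurites
#'
#' Counts and measures the detected PO regions falling in each compartment
#' of a [proximal_region()] partition (fixed-cell, single-frame analysis).
#' Region membership is decided by the centroid (avoiding double counting
#' of regions straddling a boundary); areas sum the member regions' pixel
#' areas; percent area normalizes by the compartment area.
#'
#' @param detections single-frame [detect_regions()] output (`row`, `col`,
#'   `area_um2` columns).
#' @param partition a [proximal_region()] result.
#' @return data frame with one row per region (`soma`, `proximal_neurites`):
#'   `po_count`, `po_area_um2`, `region_area_um2`, `percent_area`.
#' @export
distribution_summary <- function(detections, partition) {
  stopifnot(inherits(partition, "region_partition"))
  if (!any(partition$soma) && !any(partition$proximal))
    stop("empty region partition")
  in_mask <- function(mask) {
    if (nrow(detections) == 0) return(logical(0))
    r <- pmin(pmax(round(detections$row), 1), nrow(mask))
    c_ <- pmin(pmax(round(detections$col), 1), ncol(mask))
    mask[cbind(r, c_)]
  }
  soma_in <- in_mask(partition$soma)
  prox_in <- in_mask(partition$proximal)
  mk <- function(name, sel, region_area) {
    po_area <- if (any(sel)) sum(detections$area_um2[sel]) else 0
    data.frame(region = name, po_count = sum(sel), po_area_um2 = po_area,
               region_area_um2 = region_area,
               percent_area = if (region_area > 0) 100 * po_area / region_area
               else NA_real_)
  }
  out <- rbind(mk("soma", soma_in, partition$soma_area_um2),
               mk("proximal_neurites", prox_in, partition$proximal_area_um2))
  rownames(out) <- NULL
  out
}

#' Peroxisome-mitochondria contact fraction
#'
#' After both channels are binarized (Otsu within the analysis mask), a PO
#' region counts as a contact iff any of its pixels overlaps or is
#' 8-adjacent to a mitochondrion pixel — equivalently, overlaps the
#' mitochondria mask dilated by `dilate_px`.  Only POs whose centroid lies
#' inside the analysis region (the neurite mask; contacts are scored
#' outside the soma) enter the fraction.
#'
#' @param po_regions [detect_regions()] output for the PO channel (must
#'   carry the `labels` attribute).
#' @param mito_mask logical binarized mitochondria mask.
#' @param analysis_region logical mask restricting the analysis.
#' @param dilate_px adjacency dilation radius in pixels (default 1 px).
#' @return list of class `contact_summary`: `n_po_total`, `n_po_contact`,
#'   `contact_fraction`, `contact` (per-PO logical, aligned with the rows
#'   of `po_regions` kept in the analysis region).
#' @export
contact_fraction <- function(po_regions, mito_mask, analysis_region,
                             dilate_px = 1L) {
  lab <- attr(po_regions, "labels")
  if (is.null(lab)) stop("po_regions must carry the detection label image")
  stopifnot(all(dim(lab) == dim(mito_mask)),
            all(dim(lab) == dim(analysis_region)))
  r <- pmin(pmax(round(po_regions$row), 1), nrow(lab))
  c_ <- pmin(pmax(round(po_regions$col), 1), ncol(lab))
  inside <- analysis_region[cbind(r, c_)]
  kept <- po_regions[inside, , drop = FALSE]
  if (nrow(kept) == 0)
    stop("undefined contact fraction: no PO regions in the analysis region")
  grown <- dilate_disc(mito_mask, dilate_px)
  touched <- unique(lab[grown & lab > 0])
  contact <- kept$label %in% touched
  structure(list(n_po_total = nrow(kept), n_po_contact = sum(contact),
                 contact_fraction = mean(contact), contact = contact),
            class = "contact_summary")
}

#' One-tailed unpaired two-sample t test (pooled variance)
#'
#' The group comparison used throughout: `t = (mean(b) - mean(a)) / (s_p
#' sqrt(1/n_a + 1/n_b))` with the pooled standard deviation `s_p`, degrees
#' of freedom `n_a + n_b - 2`, and a one-tailed p value in the stated
#' direction.  Significance stars at p < 0.05 (*), < 0.01 (**), < 0.005
#' (***), < 0.001 (****).
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @param direction `"greater"` tests mean(b) > mean(a); `"less"` tests
#'   mean(b) < mean(a).
#' @param welch use the Welch (unpooled) variant instead.
#' @return list of class `group_comparison`: `t`, `df`, `p`, `stars`,
#'   `mean_a`, `mean_b`, `direction`, `degenerate` (`TRUE` for the
#'   zero-variance equal-mean convention `p = 0.5`).
#' @export
compare_groups <- function(values_a, values_b,
                           direction = c("greater", "less"),
                           welch = FALSE) {
  direction <- match.arg(direction)
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  ma <- mean(values_a); mb <- mean(values_b)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      return(structure(list(t = 0, df = na + nb - 2, p = 0.5, stars = "ns",
                            mean_a = ma, mean_b = mb, direction = direction,
                            degenerate = TRUE), class = "group_comparison"))
    }
    t_stat <- sign(mb - ma) * Inf
    df <- na + nb - 2
  } else if (welch) {
    se <- sqrt(va / na + vb / nb)
    t_stat <- (mb - ma) / se
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
    t_stat <- (mb - ma) / (sp * sqrt(1 / na + 1 / nb))
    df <- na + nb - 2
  }
  p <- if (direction == "greater") pt(t_stat, df, lower.tail = FALSE)
  else pt(t_stat, df)
  stars <- if (p < 0.001) "****" else if (p < 0.005) "***" else
    if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  structure(list(t = t_stat, df = df, p = p, stars = stars, mean_a = ma,
                 mean_b = mb, direction = direction,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-tailed unpaired t (%s): t = %.4g, df = %.4g, p = %.4g %s\n",
              x$direction, x$t, x$df, x$p, x$stars))
  invisible(x)
}
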