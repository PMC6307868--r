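#' Default run configuration
#'
#' Nested list of every tunable pipeline parameter with its default;
#' [load_run_config()] validates a user file against this schema (unknown
#' keys are rejected) and fills unset values.
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    imaging = list(pixel_size = 0.08, frame_interval = 5, n_frames = 97,
                   frame_shape = c(512L, 512L)),
    frangi = list(scales = c(1, 2, 3, 4), beta = 0.5),
    segmentation = list(neurite_width_um = 1.2, presmooth_sigma = 2,
                        soma_scales_px = c(10, 15, 20, 25, 30, 40),
                        soma_downsample = 4, soma_opening_px = 64,
                        soma_margin_px = 12),
    detection = list(po_sigma = 1, mito_sigma = 2, min_size = 4),
    tracking = list(max_link_dist = 1.0),
    motility = list(displacement_floor = 0.1, min_samples_frac = 0.9),
    distribution = list(proximal_length = 30),
    contacts = list(dilate_px = 1),
    io = list(input = NULL, output = NULL),
    seed = 1L), class = "run_config")
}

#' Load and validate a run configuration file
#'
#' Reads a YAML configuration, checks every key against the schema of
#' [default_run_config()] (unknown keys fail with the offending name),
#' and fills unset values with defaults.  An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  def <- default_run_config()
  merged <- .merge_config(def, user, "")
  class(merged) <- "run_config"
  merged
}

.merge_config <- function(def, user, prefix) {
  if (!is.list(user))
    stop("config section '", sub("^\\.", "", prefix),
         "' must be a mapping, got a scalar")
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config key: ",
         sub("^\\.", "", paste0(prefix, ".", unknown[1])))
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- .merge_config(def[[k]], user[[k]], paste0(prefix, ".", k))
    } else {
      v <- user[[k]]
      if (!is.null(def[[k]]) && is.numeric(def[[k]]) && !is.numeric(v))
        stop("config key ", sub("^\\.", "", paste0(prefix, ".", k)),
             " must be numeric")
      def[[k]] <- if (is.list(v)) unlist(v) else v
    }
  }
  def
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$io <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

# detection params per channel from a run_config
.config_det_params <- function(config) {
  list(PO = detection_params(sigma = config$detection$po_sigma,
                             min_size = config$detection$min_size),
       MITO = detection_params(sigma = config$detection$mito_sigma,
                               min_size = config$detection$min_size),
       CYTO = detection_params(sigma = config$detection$po_sigma,
                               min_size = config$detection$min_size))
}

#' Run the motility pipeline on a time-lapse acquisition
#'
#' Orchestrates segmentation, per-frame detection, tracking, per-track and
#' cohort motility statistics for every channel of a two-channel
#' time-lapse, and writes all artifacts (masks as 8-bit TIFF, detections /
#' tracks / per-track summaries as CSV, the cohort summary as JSON, and a
#' manifest with MD5 checksums) to the output directory.  Deterministic:
#' rerunning on the same input yields identical checksums.
#'
#' @param input an `image_stack_set`, or a fixture directory readable by
#'   [read_fixture()] (also accepted via `config$io$input`).
#' @param config a `run_config` (or path to one).
#' @param output output directory (default `config$io$output`).
#' @param channels channels to analyze (default: all rendered).
#' @return list with `masks`, `detections`, `tracks`, `summaries` (per
#'   channel), `cohorts` (per channel), `manifest`; written files under
#'   `output` when given.
#' @export
run_motility <- function(input = NULL, config = default_run_config(),
                         output = NULL, channels = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  if (is.null(input)) input <- config$io$input
  if (is.character(input)) input <- read_fixture(input)
  stopifnot(inherits(input, "image_stack_set"))
  if (is.null(output)) output <- config$io$output
  if (is.null(channels)) channels <- names(input$stacks)
  missing_ch <- setdiff(channels, names(input$stacks))
  if (length(missing_ch))
    stop("motility stage: channel missing from input: ", missing_ch[1])

  masks <- segment_neuron(
    input, frangi = frangi_params(config$frangi$scales, config$frangi$beta),
    neurite_width_um = config$segmentation$neurite_width_um,
    scales_px = config$segmentation$soma_scales_px,
    soma_margin_px = config$segmentation$soma_margin_px,
    presmooth_sigma = config$segmentation$presmooth_sigma)
  det <- detect_stack(input, masks, params = .config_det_params(config),
                      channels = channels)
  tracks <- list(); summaries <- list(); cohorts <- list()
  for (ch in channels) {
    dch <- det[det$channel == ch, , drop = FALSE]
    tr <- build_tracks(dch, max_link_dist = config$tracking$max_link_dist,
                       organelle = ch)
    mt <- motility_table(tr, frame_interval = input$config$frame_interval,
                         displacement_floor = config$motility$displacement_floor)
    tracks[[ch]] <- tr
    summaries[[ch]] <- mt
    full <- mt[mt$n_samples >=
                 config$motility$min_samples_frac * input$config$n_frames, ]
    cohorts[[ch]] <- if (nrow(full) > 0) cohort_summary(full) else NULL
  }
  manifest <- NULL
  if (!is.null(output)) {
    dir.create(output, recursive = TRUE, showWarnings = FALSE)
    .write_mask_tiff(masks$soma_mask, file.path(output, "soma_mask.tif"))
    .write_mask_tiff(masks$neurite_mask,
                     file.path(output, "neurite_mask.tif"))
    write.csv(det, file.path(output, "detections.csv"), row.names = FALSE)
    all_tracks <- do.call(rbind, unname(tracks))
    write.csv(all_tracks, file.path(output, "tracks.csv"),
              row.names = FALSE)
    all_sum <- do.call(rbind, lapply(names(summaries), function(ch) {
      s <- summaries[[ch]]
      attributes(s)[c("speeds", "speeds_by_track")] <- NULL
      s
    }))
    write.csv(all_sum, file.path(output, "track_summaries.csv"),
              row.names = FALSE)
    coh <- lapply(cohorts, function(co) if (is.null(co)) NULL else list(
      n_tracks = co$n_tracks, class_fractions = as.list(co$class_fractions),
      mean_avg_speed = co$mean_avg_speed,
      mean_max_speed = co$mean_max_speed,
      mean_total_distance = co$mean_total_distance))
    coh$soma_centroid <- as.numeric(masks$soma_centroid)
    jsonlite::write_json(coh, file.path(output, "cohort.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- .write_manifest(output)
  }
  invisible(list(masks = masks, detections = det, tracks = tracks,
                 summaries = summaries, cohorts = cohorts,
                 manifest = manifest))
}

.write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), path,
                  bits.per.sample = 8L, compression = "none")
}

.write_manifest <- function(output) {
  files <- setdiff(list.files(output), "manifest.json")
  sums <- tools::md5sum(file.path(output, files))
  manifest <- data.frame(file = files, md5 = unname(sums))
  jsonlite::write_json(manifest, file.path(output, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Analyze a fixed (single-frame) neuron
#'
#' Fixed-cell distribution pipeline: the morphology mask is built from the
#' cytosol-fill channel (Otsu, largest component, holes filled), the soma
#' from the DoG detector; PO regions are detected separately inside the
#' soma and proximal-neurite partitions (mask-restricted Otsu each) and
#' summarized with [distribution_summary()].
#'
#' @param stack_set an `image_stack_set` with channels `PO` and `CYTO`.
#' @param config a `run_config`.
#' @return list: `masks`, `partition`, `detections` (PO regions with a
#'   `region` column), `summary` (the [distribution_summary()] table).
#' @export
analyze_fixed_neuron <- function(stack_set, config = default_run_config()) {
  stopifnot(inherits(stack_set, "image_stack_set"))
  for (ch in c("PO", "CYTO"))
    if (is.null(stack_set$stacks[[ch]]))
      stop("fixed-cell analysis needs channel: ", ch)
  px <- stack_set$config$pixel_size
  cyto <- matrix(as.numeric(stack_set$stacks$CYTO[[1]]),
                 nrow(stack_set$stacks$CYTO[[1]]))
  sm <- gaussian_smooth(cyto, 2)
  thr <- otsu_threshold(as.vector(sm))
  cell <- largest_component(sm > thr$threshold)
  cell <- EBImage::fillHull(matrix(as.numeric(cell), nrow(cell))) > 0
  soma <- detect_soma(cyto,
                      scales_px = config$segmentation$soma_scales_px,
                      downsample = config$segmentation$soma_downsample,
                      opening_px = config$segmentation$soma_opening_px)
  masks <- finalize_masks(cell, soma,
                          soma_margin_px = config$segmentation$soma_margin_px)
  partition <- proximal_region(masks,
                               length = config$distribution$proximal_length,
                               pixel_size = px)
  po <- matrix(as.numeric(stack_set$stacks$PO[[1]]),
               nrow(stack_set$stacks$PO[[1]]))
  p <- detection_params(sigma = config$detection$po_sigma,
                        min_size = config$detection$min_size)
  det_soma <- detect_regions(po, partition$soma, p, pixel_size = px)
  det_prox <- detect_regions(po, partition$proximal, p, pixel_size = px)
  det_soma$region <- if (nrow(det_soma)) "soma" else character(0)
  det_prox$region <- if (nrow(det_prox)) "proximal_neurites" else character(0)
  detections <- rbind(det_soma, det_prox)
  list(masks = masks, partition = partition, detections = detections,
       summary = distribution_summary(detections, partition))
}

#' Measure the PO-mitochondria contact fraction of a two-channel stack
#'
#' Contact pipeline on the first frame: neuron segmentation from the
#' projections, Otsu binarization of both channels within the neurite mask,
#' then [contact_fraction()] with overlap-or-adjacency logic.
#'
#' @param stack_set an `image_stack_set` with `PO` and `MITO` channels.
#' @param config a `run_config`.
#' @return a `contact_summary` (see [contact_fraction()]).
#' @export
analyze_contacts <- function(stack_set, config = default_run_config()) {
  stopifnot(inherits(stack_set, "image_stack_set"))
  for (ch in c("PO", "MITO"))
    if (is.null(stack_set$stacks[[ch]]))
      stop("contact analysis needs channel: ", ch)
  px <- stack_set$config$pixel_size
  masks <- segment_neuron(
    stack_set,
    frangi = frangi_params(config$frangi$scales, config$frangi$beta),
    neurite_width_um = config$segmentation$neurite_width_um,
    scales_px = config$segmentation$soma_scales_px,
    soma_margin_px = config$segmentation$soma_margin_px,
    presmooth_sigma = config$segmentation$presmooth_sigma)
  po <- matrix(as.numeric(stack_set$stacks$PO[[1]]),
               nrow(stack_set$stacks$PO[[1]]))
  mito <- matrix(as.numeric(stack_set$stacks$MITO[[1]]),
                 nrow(stack_set$stacks$MITO[[1]]))
  po_det <- detect_regions(po, masks$neurite_mask,
                           detection_params(sigma = config$detection$po_sigma,
                                            min_size = config$detection$min_size),
                           pixel_size = px)
  mito_sm <- gaussian_smooth(mito, config$detection$mito_sigma)
  mito_thr <- otsu_threshold(mito_sm[masks$neurite_mask])
  mito_mask <- mito_sm > mito_thr$threshold & masks$neurite_mask
  contact_fraction(po_det, mito_mask, masks$neurite_mask,
                   dilate_px = config$contacts$dilate_px)
}

#' Run the distribution pipeline over one or two groups of fixed neurons
#'
#' Analyzes every fixture directory with [analyze_fixed_neuron()]; when two
#' groups are given, compares each distribution metric between groups with
#' the one-tailed unpaired t test.
#'
#' @param group_a,group_b character vectors of fixture directories (or
#'   lists of `image_stack_set`s); `group_b` may be `NULL`.
#' @param config a `run_config` (or path).
#' @param output optional output directory (distribution CSV + comparison
#'   JSON + manifest).
#' @param direction tested direction for `compare_groups(a, b)`.
#' @return list: `per_neuron` (long data frame of distribution summaries),
#'   `comparison` (named list of `group_comparison`s, or `NULL` with a
#'   notice when only one group is given).
#' @export
run_distribution <- function(group_a, group_b = NULL,
                             config = default_run_config(), output = NULL,
                             direction = "less") {
  if (is.character(config)) config <- load_run_config(config)
  analyze_group <- function(group, label) {
    rows <- list()
    for (i in seq_along(group)) {
      x <- group[[i]]
      if (is.character(x)) x <- read_fixture(x)
      res <- analyze_fixed_neuron(x, config)
      s <- res$summary
      s$group <- label
      s$neuron <- i
      rows[[i]] <- s
    }
    do.call(rbind, rows)
  }
  if (is.character(group_a)) group_a <- as.list(group_a)
  a <- analyze_group(group_a, "A")
  per_neuron <- a
  comparison <- NULL
  if (!is.null(group_b)) {
    if (is.character(group_b)) group_b <- as.list(group_b)
    b <- analyze_group(group_b, "B")
    per_neuron <- rbind(a, b)
    if (length(group_a) >= 2 && length(group_b) >= 2) {
      comparison <- list()
      for (reg in unique(per_neuron$region)) {
        for (metric in c("po_count", "po_area_um2", "percent_area")) {
          va <- a[a$region == reg, metric]
          vb <- b[b$region == reg, metric]
          if (all(is.finite(va)) && all(is.finite(vb)))
            comparison[[paste(reg, metric, sep = ".")]] <-
              compare_groups(va, vb, direction = direction)
        }
      }
    } else {
      message("comparison skipped: need >= 2 neurons per group")
    }
  } else {
    message("single group given; comparison skipped")
  }
  if (!is.null(output)) {
    dir.create(output, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_neuron, file.path(output, "distribution.csv"),
              row.names = FALSE)
    if (!is.null(comparison)) {
      cj <- lapply(comparison, function(x)
        list(t = x$t, df = x$df, p = x$p, stars = x$stars,
             mean_a = x$mean_a, mean_b = x$mean_b))
      jsonlite::write_json(cj, file.path(output, "comparison.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    .write_manifest(output)
  }
  list(per_neuron = per_neuron, comparison = comparison)
}
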