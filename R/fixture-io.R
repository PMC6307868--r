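#' Write a simulated acquisition to disk
#'
#' Serializes an `image_stack_set` as one multi-page 16-bit TIFF per channel
#' (pages = frames, integer counts), a `metadata.json` recording the pixel
#' size, frame interval and channel layout (the installed TIFF writer does
#' not persist custom tags, so acquisition metadata lives in this sidecar
#' file alongside the images), a `tracks.csv` with the planted trajectories
#' when present, and a `ground_truth.json` with the remaining planted
#' values.  Re-reading with [read_fixture()] reproduces the pixel arrays
#' bit-exactly and the metadata at full precision.
#'
#' @param stack_set an `image_stack_set` (from [render_timelapse()],
#'   [render_fixed_neuron()] or [make_contact_fixture()]).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(stack_set, dir) {
  stopifnot(inherits(stack_set, "image_stack_set"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create fixture directory: ", dir)
  cfg <- stack_set$config
  for (ch in names(stack_set$stacks)) {
    pages <- lapply(stack_set$stacks[[ch]], function(f) f / 65535)
    path <- file.path(dir, paste0(ch, ".tif"))
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                   compression = "none"),
                   error = function(e)
                     stop("failed to write ", path, ": ",
                          conditionMessage(e)))
  }
  meta <- list(pixel_size_um = cfg$pixel_size,
               frame_interval_s = cfg$frame_interval,
               n_frames = length(stack_set$stacks[[1]]),
               frame_shape = cfg$frame_shape,
               channels = names(stack_set$stacks),
               count_scale = 65535)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- stack_set$truth
  tracks <- .truth_track_table(truth)
  if (!is.null(tracks))
    write.csv(tracks, file.path(dir, "tracks.csv"), row.names = FALSE)
  gt <- .truth_json(truth)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.truth_track_table <- function(truth) {
  parts <- list()
  for (nm in c("po", "mito")) {
    gt <- truth[[nm]]
    if (inherits(gt, "ground_truth_tracks")) {
      tab <- merge(gt$table[, c("track_id", "organelle", "frame", "x_um",
                                "y_um", "s_um", "neurite_index")],
                   gt$summary[, c("track_id", "planted_class")],
                   by = "track_id")
      parts[[nm]] <- tab[order(tab$track_id, tab$frame), ]
    }
  }
  if (length(parts)) do.call(rbind, parts) else NULL
}

.truth_json <- function(truth) {
  out <- list()
  for (nm in c("po", "mito")) {
    gt <- truth[[nm]]
    if (inherits(gt, "ground_truth_tracks"))
      out[[paste0(nm, "_summary")]] <- gt$summary
    else if (is.data.frame(gt)) out[[nm]] <- gt
  }
  if (!is.null(truth$planted_fraction))
    out$planted_fraction <- truth$planted_fraction
  if (!is.null(truth$planted)) out$planted <- truth$planted
  if (!is.null(truth$spots)) out$spots <- truth$spots
  if (!is.null(truth$seed)) out$seed <- truth$seed
  out
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return an `image_stack_set` with integer count frames, the
#'   reconstructed [imaging_config()] and the deserialized ground truth
#'   (`$truth$tracks` data frame and `$truth$json` list, when present).
#' @export
read_fixture <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path))
    stop("not a fixture directory (missing metadata.json): ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cfg <- imaging_config(pixel_size = as.numeric(meta$pixel_size_um),
                        frame_interval = as.numeric(meta$frame_interval_s),
                        n_frames = max(meta$n_frames, 2),
                        frame_shape = meta$frame_shape,
                        channels = meta$channels)
  cfg$n_frames <- as.integer(meta$n_frames)
  stacks <- list()
  for (ch in meta$channels) {
    path <- file.path(dir, paste0(ch, ".tif"))
    if (!file.exists(path)) stop("missing channel file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    stacks[[ch]] <- lapply(pages, function(p)
      matrix(as.integer(round(p * meta$count_scale)), nrow(p)))
  }
  truth <- list()
  tr_path <- file.path(dir, "tracks.csv")
  if (file.exists(tr_path)) truth$tracks <- read.csv(tr_path)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path))
    truth$json <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  structure(list(stacks = stacks, config = cfg, truth = truth),
            class = "image_stack_set")
}
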