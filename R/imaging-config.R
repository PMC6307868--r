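#' Imaging configuration
#'
#' Physical acquisition parameters shared by the simulator and the analysis
#' pipeline: confocal time-lapse recordings of cultured hippocampal neurons
#' sampled at a fixed pixel size, with frames a few seconds apart over a
#' session of about eight minutes.
#'
#' @param pixel_size physical pixel size, micrometres per pixel (> 0).
#' @param frame_interval time between frames in seconds (> 0).
#' @param n_frames number of frames (>= 2); the default 97 frames at 5 s give
#'   a 480 s (8 min) session.
#' @param frame_shape frame dimensions in pixels, `c(rows, cols)`.
#' @param channels ordered channel labels.
#' @return an object of class `imaging_config`.
#' @examples
#' cfg <- imaging_config()
#' session_duration(cfg)  # 480 s
#' @export
imaging_config <- function(pixel_size = 0.08, frame_interval = 5,
                           n_frames = 97, frame_shape = c(512L, 512L),
                           channels = c("PO", "MITO")) {
  stopifnot(pixel_size > 0, frame_interval > 0, n_frames >= 2,
            length(frame_shape) == 2, all(frame_shape >= 16))
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 frame_shape = as.integer(frame_shape),
                 channels = channels),
            class = "imaging_config")
}

#' @rdname imaging_config
#' @param config an `imaging_config`.
#' @export
session_duration <- function(config) {
  (config$n_frames - 1) * config$frame_interval
}

#' @export
print.imaging_config <- function(x, ...) {
  cat(sprintf(
    "imaging_config: %d frames of %dx%d px, %.3g um/px, %.3g s interval (%g s session)\n",
    x$n_frames, x$frame_shape[1], x$frame_shape[2], x$pixel_size,
    x$frame_interval, session_duration(x)))
  invisible(x)
}

#' Motility presets
#'
#' Class mixtures and run speeds describing the saltatory run/pause motion of
#' organelles in neurites.  The four classes are defined by total travelled
#' distance over the session: static (< 1 um), very short range (1-5 um),
#' short range (5-10 um) and long range (>= 10 um).  The named presets are
#' the published cohort mixtures: untreated-neuron peroxisomes
#' (`"control-PO"`, 1/59/30/10 %), peroxisomes under ACBD5 overexpression
#' (`"acbd5-PO"`, 3/81/14/2 %) and untreated mitochondria (`"control-MITO"`,
#' 75/5/5/15 %), with maximal run speeds of 0.1 um/s for peroxisomes and
#' 0.06 um/s for mitochondria.
#'
#' @param name one of `"control-PO"`, `"acbd5-PO"`, `"control-MITO"`, or
#'   `NULL` to build a custom preset from the remaining arguments.
#' @param class_probs probabilities over (static, very_short, short, long);
#'   must sum to 1.
#' @param run_speed run (saltatory burst) speed in um/s (> 0).
#' @param class_distance_bounds 4x2 matrix of per-class half-open distance
#'   intervals in um; the long-range upper bound closes the open `>= 10 um`
#'   class for simulation purposes.
#' @param oscillation_step magnitude of small oscillatory steps in um.
#' @param organelle channel the preset describes (`"PO"` or `"MITO"`).
#' @return an object of class `motility_preset`.
#' @export
motility_preset <- function(name = NULL, class_probs = NULL, run_speed = NULL,
                            class_distance_bounds = NULL,
                            oscillation_step = 0.15, organelle = NULL) {
  named <- list(
    "control-PO"   = list(p = c(0.01, 0.59, 0.30, 0.10), v = 0.1,  org = "PO"),
    "acbd5-PO"     = list(p = c(0.03, 0.81, 0.14, 0.02), v = 0.1,  org = "PO"),
    "control-MITO" = list(p = c(0.75, 0.05, 0.05, 0.15), v = 0.06, org = "MITO"))
  if (!is.null(name)) {
    if (!name %in% names(named))
      stop("unknown motility preset: ", name)
    def <- named[[name]]
    if (is.null(class_probs)) class_probs <- def$p
    if (is.null(run_speed)) run_speed <- def$v
    if (is.null(organelle)) organelle <- def$org
  }
  if (is.null(organelle)) organelle <- "PO"
  if (is.null(class_distance_bounds))
    class_distance_bounds <- matrix(c(0, 1, 1, 5, 5, 10, 10, 15), ncol = 2,
                                    byrow = TRUE)
  stopifnot(length(class_probs) == 4, abs(sum(class_probs) - 1) < 1e-8,
            run_speed > 0, oscillation_step > 0,
            nrow(class_distance_bounds) == 4)
  if (!all(class_distance_bounds[, 1] == c(0, 1, 5, 10)))
    stop("class_distance_bounds must match the motility classification intervals")
  rownames(class_distance_bounds) <- motility_class_levels()
  structure(list(name = name, class_probs = class_probs,
                 run_speed = run_speed,
                 class_distance_bounds = class_distance_bounds,
                 oscillation_step = oscillation_step, organelle = organelle),
            class = "motility_preset")
}

#' Contact-planting preset
#'
#' Probability that a planted peroxisome is placed in contact with (on top
#' of, or within 0.1 um of the boundary of) a mitochondrion; all other
#' peroxisomes are kept at least `clearance` away from any mitochondrion.
#' The named preset `"contact-control"` plants the published control contact
#' fraction of 84.6 %.
#'
#' @param name `"contact-control"` or `NULL`.
#' @param contact_fraction probability of planting a PO in contact (0..1).
#' @param clearance minimum PO-to-mitochondrion boundary distance for planted
#'   non-contacts, um.
#' @return an object of class `contact_preset`.
#' @export
contact_preset <- function(name = NULL, contact_fraction = NULL,
                           clearance = 1) {
  if (!is.null(name)) {
    if (name != "contact-control") stop("unknown contact preset: ", name)
    if (is.null(contact_fraction)) contact_fraction <- 0.846
  }
  stopifnot(contact_fraction >= 0, contact_fraction <= 1, clearance > 0)
  structure(list(name = name, contact_fraction = contact_fraction,
                 clearance = clearance),
            class = "contact_preset")
}

#' Fixed-neuron fixture specification
#'
#' Spot counts and total areas for a single fixed (immunostained) neuron:
#' peroxisomes in the soma and in the proximal 30 um of the neurites,
#' rendered together with a cytosol-fill channel used as the morphology
#' reference.  Named presets carry the published group means: control
#' neurons with 174 somatic and 65 proximal-neurite POs covering 22 and
#' 6 um^2, and ACBD5-overexpressing neurons with 88 and 99 POs covering 11
#' and 11 um^2.
#'
#' @param name `"fixed-control"`, `"fixed-acbd5"`, or `NULL` for a custom
#'   spec built from the remaining arguments.
#' @param soma_po_count,neurite_po_count planted spot counts.
#' @param soma_po_area,neurite_po_area planted total spot areas, um^2.
#' @param min_spot_separation minimum clear distance between spot boundaries,
#'   um (centre distance >= `2 * r_spot + min_spot_separation`).
#' @return an object of class `fixed_neuron_spec`.
#' @export
fixed_neuron_spec <- function(name = NULL, soma_po_count = NULL,
                              neurite_po_count = NULL, soma_po_area = NULL,
                              neurite_po_area = NULL,
                              min_spot_separation = 0.5) {
  named <- list(
    "fixed-control" = list(sc = 174L, nc = 65L, sa = 22, na = 6),
    "fixed-acbd5"   = list(sc = 88L,  nc = 99L, sa = 11, na = 11))
  if (!is.null(name)) {
    if (!name %in% names(named)) stop("unknown fixed-neuron preset: ", name)
    def <- named[[name]]
    if (is.null(soma_po_count)) soma_po_count <- def$sc
    if (is.null(neurite_po_count)) neurite_po_count <- def$nc
    if (is.null(soma_po_area)) soma_po_area <- def$sa
    if (is.null(neurite_po_area)) neurite_po_area <- def$na
  }
  stopifnot(soma_po_count >= 0, neurite_po_count >= 0, soma_po_area >= 0,
            neurite_po_area >= 0, min_spot_separation >= 0)
  structure(list(name = name, soma_po_count = as.integer(soma_po_count),
                 neurite_po_count = as.integer(neurite_po_count),
                 soma_po_area = soma_po_area, neurite_po_area = neurite_po_area,
                 min_spot_separation = min_spot_separation),
            class = "fixed_neuron_spec")
}

#' Motility class levels
#' @return character vector of the four motility class labels, ordered.
#' @export
motility_class_levels <- function() c("static", "very_short", "short", "long")
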