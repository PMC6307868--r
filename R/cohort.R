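#' Simulate and analyze a cohort of neurons end-to-end
#'
#' The parameter-recovery workhorse: for each neuron it generates a
#' geometry, plants tracks from the motility preset, renders the
#' time-lapse, then runs the full measurement pipeline — segmentation
#' ([segment_neuron()]), per-frame detection ([detect_stack()]), tracking
#' ([build_tracks()]) and per-track statistics ([motility_table()]) — and
#' pools planted and measured results.
#'
#' Cohort statistics are computed over measured tracks spanning at least
#' `min_samples_frac` of the session (a minimum track-duration filter:
#' broken fragments otherwise dilute the class fractions; the filter is the
#' package's analysis choice and is reported alongside the results).
#'
#' @param preset a [motility_preset()] (or preset name).
#' @param n_neurons number of neurons to simulate.
#' @param n_organelles tracks planted per neuron.
#' @param config an [imaging_config()].
#' @param seed integer base seed; neuron `i` uses `seed * 1000 + i` offsets.
#' @param noise a [noise_params()].
#' @param min_samples_frac minimum fraction of frames a measured track must
#'   span to enter the cohort summary.
#' @param max_link_dist tracking gate, um per frame.
#' @param displacement_floor um, see [track_statistics()].
#' @return list of class `cohort_run`: `planted` (pooled planted track
#'   summaries), `measured` (all measured tracks), `measured_full`
#'   (duration-filtered), `cohort` ([cohort_summary()] of the filtered
#'   tracks), `preset`, `n_neurons`.
#' @export
run_simulated_cohort <- function(preset, n_neurons = 21L, n_organelles = 25L,
                                 config = imaging_config(), seed = 1L,
                                 noise = noise_params(),
                                 min_samples_frac = 0.9,
                                 max_link_dist = 1.0,
                                 displacement_floor = 0.1) {
  if (is.character(preset)) preset <- motility_preset(preset)
  planted <- list(); measured <- list(); speeds_all <- list()
  for (i in seq_len(n_neurons)) {
    base <- seed * 1000 + i
    g <- make_geometry(config, n_neurites = 5L, seed = base)
    gt <- sample_tracks(g, preset, n_organelles, config, seed = base + 211L)
    po <- if (preset$organelle == "PO") gt else NULL
    mito <- if (preset$organelle == "MITO") gt else NULL
    st <- render_timelapse(g, po_tracks = po, mito_tracks = mito,
                           config = config, noise = noise,
                           seed = base + 500L)
    masks <- segment_neuron(st)
    det <- detect_stack(st, masks, channels = preset$organelle)
    tr <- build_tracks(det, max_link_dist = max_link_dist,
                       organelle = preset$organelle)
    mt <- motility_table(tr, frame_interval = config$frame_interval,
                         displacement_floor = displacement_floor)
    sp_by <- attr(mt, "speeds_by_track")
    if (nrow(mt) > 0) {
      mt$neuron <- i
      mt$track_uid <- i * 100000L + mt$track_id
      names(sp_by) <- mt$track_uid
    }
    speeds_all[[i]] <- sp_by
    sm <- gt$summary
    sm$neuron <- i
    planted[[i]] <- sm
    measured[[i]] <- mt
  }
  planted <- do.call(rbind, planted)
  measured <- do.call(rbind, measured)
  speeds_all <- do.call(c, speeds_all)
  full <- measured[measured$n_samples >= min_samples_frac * config$n_frames, ]
  if (nrow(full) > 0)
    attr(full, "speeds") <-
      unlist(speeds_all[as.character(full$track_uid)], use.names = FALSE)
  structure(list(planted = planted, measured = measured,
                 measured_full = full,
                 cohort = if (nrow(full) > 0) cohort_summary(full) else NULL,
                 preset = preset, n_neurons = n_neurons, seed = seed),
            class = "cohort_run")
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("cohort_run: %d neurons, preset %s; %d planted, %d measured (%d full-length)\n",
              x$n_neurons, x$preset$name %||% "custom", nrow(x$planted),
              nrow(x$measured), nrow(x$measured_full)))
  if (!is.null(x$cohort)) print(x$cohort)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean maximum instantaneous speed of moving tracks
#'
#' Restricts a measured cohort to tracks that performed at least one
#' saltatory run — operationally, tracks whose maximum instantaneous speed
#' exceeds `moving_threshold` (above the oscillation-step plateau of
#' `oscillation_step / frame_interval` = 0.03 um/s at defaults, below the
#' run speed) — and returns the mean of their per-track maximum speeds.
#'
#' @param summaries a [motility_table()] result.
#' @param moving_threshold um/s.
#' @return mean of per-track max speeds over moving tracks (`NaN` when no
#'   track qualifies).
#' @export
mean_moving_max_speed <- function(summaries, moving_threshold = 0.05) {
  sel <- summaries$max_speed >= moving_threshold
  mean(summaries$max_speed[sel])
}
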