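#' Plant peroxisome-mitochondria contacts
#'
#' Given mitochondria footprints already laid along the neurites, draws a
#' Bernoulli contact label for each requested peroxisome and assigns
#' positions: planted contacts sit on top of a mitochondrion (centre inside
#' the footprint), planted non-contacts keep at least `clearance` between
#' the peroxisome and any mitochondrion boundary.  Peroxisomes are spaced
#' at least 0.8 um apart so they remain individually resolvable.
#'
#' @param n_po number of peroxisomes to plant.
#' @param mito_footprints data frame with columns `neurite`, `s_start`,
#'   `s_end` (arc-length extent of each mitochondrion, um) as produced by
#'   [make_contact_fixture()] internals.
#' @param geometry a [make_geometry()] result (for neurite lengths).
#' @param preset a [contact_preset()].
#' @param seed integer RNG seed.
#' @param boundary_halo extent of the rendered mitochondrion beyond its
#'   segment, um (rendered soft edge), added to clearance computations.
#' @return data frame with one row per PO: `neurite`, `s_um`, `contact`
#'   (logical planted label).  The planted fraction is `mean(contact)`.
#' @export
plant_contacts <- function(n_po, mito_footprints, geometry, preset,
                           seed = 1L, boundary_halo = 0.3) {
  stopifnot(inherits(preset, "contact_preset"), n_po >= 1)
  set.seed(seed)
  labels <- runif(n_po) < preset$contact_fraction
  n_c <- sum(labels); n_nc <- n_po - n_c

  po_sep <- 0.8
  contact_sites <- list()
  for (i in seq_len(nrow(mito_footprints))) {
    m <- mito_footprints[i, ]
    s <- seq(m$s_start + 0.25, m$s_end - 0.25, by = po_sep)
    if (length(s))
      contact_sites[[i]] <- data.frame(neurite = m$neurite, s_um = s)
  }
  contact_sites <- do.call(rbind, contact_sites)

  cl <- preset$clearance + boundary_halo
  nc_sites <- list()
  arcs_len <- vapply(seq_along(geometry$neurite_paths),
                     function(i) neurite_arclength(geometry, i)$length_um,
                     numeric(1))
  for (ni in seq_along(arcs_len)) {
    fp <- mito_footprints[mito_footprints$neurite == ni, , drop = FALSE]
    fp <- fp[order(fp$s_start), , drop = FALSE]
    lo <- c(2, fp$s_end + cl)
    hi <- c(fp$s_start - cl, arcs_len[ni] - 1)
    for (g in seq_along(lo)) {
      if (hi[g] - lo[g] >= 0) {
        s <- seq(lo[g], hi[g], by = po_sep)
        if (length(s))
          nc_sites[[length(nc_sites) + 1L]] <-
            data.frame(neurite = ni, s_um = s)
      }
    }
  }
  nc_sites <- do.call(rbind, nc_sites)

  if (is.null(contact_sites) || nrow(contact_sites) < n_c)
    stop("insufficient room: ", n_c, " planted contacts need more ",
         "mitochondria footprint than available")
  if (n_nc > 0 && (is.null(nc_sites) || nrow(nc_sites) < n_nc))
    stop("insufficient room: ", n_nc, " planted non-contacts need more ",
         "mitochondria-free neurite than available")

  pick_c <- contact_sites[sample.int(nrow(contact_sites), n_c), , drop = FALSE]
  out <- data.frame(neurite = integer(n_po), s_um = numeric(n_po),
                    contact = labels)
  out[labels, c("neurite", "s_um")] <- pick_c
  if (n_nc > 0) {
    pick_n <- nc_sites[sample.int(nrow(nc_sites), n_nc), , drop = FALSE]
    out[!labels, c("neurite", "s_um")] <- pick_n
  }
  out
}

#' Build a two-channel contact fixture
#'
#' Lays static mitochondria (2-3.5 um capsules) densely along the neurites
#' of a synthetic neuron, interleaving occasional mitochondria-free gaps
#' wide enough to host planted non-contact peroxisomes, then plants `n_po`
#' peroxisomes via [plant_contacts()] and renders both channels (two
#' identical-statistics frames, so the stack is a valid minimal time-lapse).
#'
#' @param preset a [contact_preset()].
#' @param n_po number of peroxisomes.
#' @param config an [imaging_config()]; defaults to a 1024 x 1024 px
#'   two-frame acquisition matching the fixed-cell field of view.
#' @param seed integer RNG seed.
#' @param noise a [noise_params()].
#' @return an `image_stack_set` with channels `PO` and `MITO`;
#'   `$truth$po` carries the planted per-PO contact labels and
#'   `$truth$planted_fraction` the realized planted fraction.
#' @export
make_contact_fixture <- function(preset = contact_preset("contact-control"),
                                 n_po = 200L,
                                 config = imaging_config(
                                   n_frames = 2, frame_shape = c(1024L, 1024L)),
                                 seed = 1L, noise = noise_params()) {
  set.seed(seed)
  geometry <- make_geometry(config, n_neurites = 5L, seed = seed + 211L,
                            neurite_length = 60)
  arcs <- lapply(seq_along(geometry$neurite_paths),
                 function(i) neurite_arclength(geometry, i))
  # expected site demand, with margin
  exp_nc <- n_po * (1 - preset$contact_fraction)
  cl_gap <- 2 * (preset$clearance + 0.3) + 0.8   # gap hosting one nc site
  mito <- list()
  nc_gap_budget <- ceiling(exp_nc * 1.6) + 4
  for (ni in seq_along(arcs)) {
    cursor <- 2.5
    end <- arcs[[ni]]$length_um - 1.5
    while (TRUE) {
      len <- runif(1, 2, 3.5)
      if (cursor + len > end) break
      mito[[length(mito) + 1L]] <-
        data.frame(neurite = ni, s_start = cursor, s_end = cursor + len)
      cursor <- cursor + len
      if (nc_gap_budget > 0 && runif(1) < 0.5) {
        cursor <- cursor + cl_gap
        nc_gap_budget <- nc_gap_budget - 1L
      } else {
        cursor <- cursor + 1.0
      }
    }
  }
  mito <- do.call(rbind, mito)
  po <- plant_contacts(n_po, mito, geometry, preset, seed = seed + 1L)

  # render
  px <- config$pixel_size
  bg <- render_background(geometry, noise)
  sigma_px <- noise$spot_sigma_um / px
  po_frame <- bg
  po$row <- NA_real_; po$col <- NA_real_
  for (i in seq_len(nrow(po))) {
    pt <- arcs[[po$neurite[i]]]$point_at(po$s_um[i])
    po_frame <- stamp_spot(po_frame, pt$row, pt$col, noise$spot_peak,
                           sigma_px)
    po$row[i] <- pt$row; po$col[i] <- pt$col
  }
  mito_frame <- bg
  for (i in seq_len(nrow(mito))) {
    mid <- (mito$s_start[i] + mito$s_end[i]) / 2
    pt <- arcs[[mito$neurite[i]]]$point_at(mid)
    mito_frame <- stamp_capsule(mito_frame, pt$row, pt$col,
                                pt$tangent[1], pt$tangent[2],
                                noise$mito_peak,
                                (mito$s_end[i] - mito$s_start[i]) / 2 / px)
  }
  stacks <- list(PO = lapply(seq_len(config$n_frames),
                             function(t) apply_noise(po_frame, noise)),
                 MITO = lapply(seq_len(config$n_frames),
                               function(t) apply_noise(mito_frame, noise)))
  structure(list(stacks = stacks, config = config,
                 truth = list(po = po, mito = mito, geometry = geometry,
                              preset = preset, noise = noise, seed = seed,
                              planted_fraction = mean(po$contact))),
            class = "image_stack_set")
}
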