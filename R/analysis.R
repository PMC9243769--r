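# Post-processing of trajectories into the model's observables: rotation /
# proton-flux coupling, deprotonation-count statistics, DEP-state labels,
# leak detection, and the four-phase cycle decomposition of each c-subunit.

# parse the per-phase protonation strings into an (n_phases x n_sites) 0/1 matrix
.h_matrix <- function(traj) {
  hm <- do.call(rbind, lapply(strsplit(traj$phases$h, ""), as.integer))
  colnames(hm) <- names(protonation_state(traj$geom))
  hm
}

#' Distribution of simultaneously deprotonated c-sites
#'
#' Counts the deprotonated c-ring carriers (channel sites excluded) in each
#' post-burn-in phase and reports the histogram and the modal count — the
#' operational "ground state" occupancy of the rotating motor.
#'
#' @param traj An `fo_trajectory`.
#' @param burn_in Phases to discard; defaults to the config value.
#' @return List with `histogram` (named counts over 0..n_c), `mode`
#'   (smallest modal count), `tie` (TRUE if the mode is not unique), and
#'   `counts` (the per-phase series).
#' @export
deprotonation_count_stats <- function(traj, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- traj$config$burn_in
  ph <- traj$phases
  if (nrow(ph) <= burn_in) stop("trajectory not longer than burn_in")
  counts <- ph$n_dep_c[ph$phase > burn_in]
  hist <- table(factor(counts, levels = 0:traj$geom$n_c))
  peak <- which(hist == max(hist))
  list(histogram = hist, mode = as.integer(names(hist)[peak[1]]),
       tie = length(peak) > 1L, counts = counts)
}

#' DEP-state label of each phase
#'
#' The sorted set of deprotonated c-subunit letters, e.g. `"b+c"` for
#' DEP(c_b, c_c); `""` for the fully protonated ring.
#'
#' @inheritParams deprotonation_count_stats
#' @return Character vector, one label per post-burn-in phase.
#' @export
dep_state_labels <- function(traj, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- traj$config$burn_in
  hm <- .h_matrix(traj)[traj$phases$phase > burn_in, , drop = FALSE]
  n_c <- traj$geom$n_c
  apply(hm[, seq_len(n_c), drop = FALSE], 1, function(row) {
    paste(letters[seq_len(n_c)][row == 1L], collapse = "+")
  })
}

# site-id lookup helpers
.role_id <- function(geom, role) geom$sites$site_id[geom$sites$role == role]
.subunit_id <- function(geom, label) {
  geom$sites$site_id[geom$sites$role == "c_carrier" &
                       geom$sites$subunit_label == label]
}

#' Net protons delivered to the matrix channel
#'
#' Signed count over accepted events: transfers from a c-carrier to the
#' matrix-channel glutamate count +1, the reverse -1. Under the synthesis
#' sign convention (positive rotation, IMS-to-matrix proton flow) a driven
#' wild-type run gives a positive net flux of about one proton per 36 deg of
#' rotation. The analogous IMS-side uptake count is attached as attribute
#' `ims_uptake`.
#'
#' @param events Event log (the `events` element of an `fo_trajectory`).
#' @param geom The matching `fo_geometry`.
#' @return Integer net matrix delivery, with attribute `ims_uptake`.
#' @export
net_flux <- function(events, geom) {
  acc <- events[events$accepted, , drop = FALSE]
  mat <- .role_id(geom, "channel_matrix")
  ims <- .role_id(geom, "channel_ims")
  c_ids <- geom$sites$site_id[geom$sites$role == "c_carrier"]
  matrix_net <- sum(acc$donor %in% c_ids & acc$acceptor == mat) -
    sum(acc$donor == mat & acc$acceptor %in% c_ids)
  ims_net <- sum(acc$donor == ims & acc$acceptor %in% c_ids) -
    sum(acc$donor %in% c_ids & acc$acceptor == ims)
  structure(matrix_net, ims_uptake = ims_net)
}

#' Count proton leaks
#'
#' Two leak channels are counted: (1) accepted transfers whose donor and
#' acceptor straddled the conserved arginine (impossible in the wild type,
#' where the gate zeroes their weight); (2) leak itineraries — a c-subunit
#' that takes a proton from one half-channel and hands it to the other
#' half-channel while the ring rotated less than `window` degrees in
#' between, i.e. a proton crossed the membrane without driving a rotation
#' step.
#'
#' @param events Event log of an `fo_trajectory`.
#' @param traj The `fo_trajectory` (for per-phase cumulative angles and the
#'   geometry).
#' @param window Maximum absolute ring rotation (degrees) between uptake
#'   and release for the pair to count as an itinerary leak.
#' @return List with `straddle`, `itinerary` and `total` counts.
#' @export
detect_leaks <- function(events, traj, window = 10) {
  geom <- traj$geom
  straddle <- sum(events$accepted & events$leak_flag)
  acc <- events[events$accepted, , drop = FALSE]
  mat <- .role_id(geom, "channel_matrix")
  ims <- .role_id(geom, "channel_ims")
  chan <- c(ims, mat)
  phic <- traj$phases$phi_cumulative
  itinerary <- 0L
  for (cid in geom$sites$site_id[geom$sites$role == "c_carrier"]) {
    sub <- acc[acc$donor == cid | acc$acceptor == cid, , drop = FALSE]
    sub <- sub[sub$donor %in% chan | sub$acceptor %in% chan, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$phase_index), , drop = FALSE]
    for (k in seq_len(nrow(sub) - 1L)) {
      up <- sub[k, ]; dn <- sub[k + 1L, ]
      took <- up$acceptor == cid && up$donor %in% chan
      gave <- dn$donor == cid && dn$acceptor %in% chan
      if (took && gave && up$donor != dn$acceptor) {
        rot <- abs(phic[dn$phase_index] - phic[up$phase_index])
        if (rot < window) itinerary <- itinerary + 1L
      }
    }
  }
  list(straddle = straddle, itinerary = itinerary,
       total = straddle + itinerary)
}

#' Four-phase cycle decomposition of one c-subunit
#'
#' Partitions the post-burn-in trajectory of one subunit into the cycle
#' resting -> proton release -> deprotonated rotation -> proton uptake.
#' The release segment runs from the subunit's entry into the
#' release-competent region (within transfer range of the matrix channel)
#' to its accepted release; the uptake segment is defined symmetrically
#' around the accepted uptake (within range of the IMS channel); the
#' deprotonated-rotation segment is the deprotonated interval between them;
#' everything else is resting.
#'
#' @param traj An `fo_trajectory`.
#' @param subunit Subunit letter.
#' @param burn_in Phases to discard; defaults to the config value.
#' @param r_max Transfer-competence range, Angstrom; defaults to the run's
#'   MC setting.
#' @return data.frame of segments (subunit, phase_kind, start, end, length);
#'   zero rows (with a message) if the subunit never completes a cycle.
#' @export
four_phase_decomposition <- function(traj, subunit, burn_in = NULL,
                                     r_max = NULL) {
  geom <- traj$geom
  if (is.null(burn_in)) burn_in <- traj$config$burn_in
  if (is.null(r_max)) r_max <- traj$config$mc$r_max
  cid <- .subunit_id(geom, subunit)
  if (length(cid) != 1L) stop("unknown subunit: ", subunit)

  keep <- traj$phases$phase > burn_in
  phases <- traj$phases$phase[keep]
  hm <- .h_matrix(traj)[keep, , drop = FALSE]
  h <- hm[, match(subunit, colnames(hm))]

  # distance of the subunit to each channel at the recorded angles
  s <- geom$sites
  crow <- s[s$site_id == cid, ]
  body_az <- .body_azimuth(crow)
  rc <- sqrt(crow$x^2 + crow$y^2)
  dist_to <- function(role) {
    a <- s[s$role == role, ]
    ra <- sqrt(a$x^2 + a$y^2)
    daz <- deg2rad(traj$phases$phi[keep] + body_az - .body_azimuth(a))
    sqrt(rc^2 + ra^2 - 2 * rc * ra * cos(daz) + (crow$z - a$z)^2)
  }
  comp_rel <- dist_to("channel_matrix") <= r_max
  comp_up <- dist_to("channel_ims") <= r_max

  n <- length(h)
  rel_t <- which(diff(h) == 1L) + 1L   # 0 -> 1: proton released
  up_t <- which(diff(h) == -1L) + 1L   # 1 -> 0: proton taken up
  kinds <- rep("resting", n)
  cycles <- 0L
  for (t_rel in rel_t) {
    t_up <- up_t[up_t > t_rel]
    if (length(t_up) == 0L) break
    t_up <- t_up[1]
    cycles <- cycles + 1L
    # release: back through the contiguous release-competent run
    start_rel <- t_rel
    while (start_rel > 1L && comp_rel[start_rel - 1L] && h[start_rel - 1L] == 0L) {
      start_rel <- start_rel - 1L
    }
    # uptake: back through the contiguous uptake-competent deprotonated run
    start_up <- t_up
    while (start_up > t_rel + 1L && comp_up[start_up - 1L] && h[start_up - 1L] == 1L) {
      start_up <- start_up - 1L
    }
    kinds[start_rel:(t_rel - 1L)] <- "release"
    if (start_up > t_rel) kinds[t_rel:(start_up - 1L)] <- "deprotonated_rotation"
    kinds[start_up:(t_up - 1L)] <- "uptake"
  }
  if (cycles == 0L) {
    message("subunit ", subunit, " never completes a release/uptake cycle")
    return(data.frame(subunit = character(0), phase_kind = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  # compress consecutive equal kinds into segments
  brk <- c(0L, which(kinds[-1] != kinds[-n]), n)
  segs <- data.frame(
    subunit = subunit,
    phase_kind = kinds[brk[-length(brk)] + 1L],
    start = phases[brk[-length(brk)] + 1L],
    end = phases[brk[-1]],
    stringsAsFactors = FALSE)
  segs$length <- segs$end - segs$start + 1L
  segs
}

#' Free-energy curve along the ring angle from sampled angles
#'
#' \eqn{F(\phi) = -\ln} of the normalized angle histogram (kBT), shifted so
#' the minimum is zero. Empty bins are masked (NA), not interpolated.
#' Curves for different fixed protonation states can be aligned by adding
#' their [bar_delta_f()] offsets.
#'
#' @param phi Sampled ring angles, degrees (wrapped internally).
#' @param bin_width Histogram bin width, degrees (must divide 360).
#' @return data.frame with bin midpoints `phi`, counts, and `f` (kBT).
#' @export
fes_angle <- function(phi, bin_width = 2) {
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  breaks <- seq(0, 360, by = bin_width)
  cnt <- table(cut(wrap360(phi), breaks = breaks, include.lowest = TRUE))
  cnt <- as.integer(cnt)
  f <- ifelse(cnt > 0, -log(cnt / sum(cnt) / bin_width), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  data.frame(phi = breaks[-length(breaks)] + bin_width / 2,
             count = cnt, f = f)
}

#' Direct Boltzmann free-energy curve of the rigid rotor
#'
#' Reference curve for cross-checking [fes_angle()]: evaluates the
#' angle-dependent potential on a grid and returns it shifted to zero
#' minimum (for a single rotor coordinate the potential is the free
#' energy).
#'
#' @param state A [protonation_state()].
#' @param geom The `fo_geometry`.
#' @param energy An [energy_params()].
#' @param grid Angle grid, degrees.
#' @return data.frame with `phi` and `f` (kBT).
#' @export
potential_profile <- function(state, geom, energy,
                              grid = seq(0, 359.5, by = 0.5)) {
  v <- vapply(grid, function(p) .v_state(state, geom, ring_state(p), energy),
              numeric(1))
  data.frame(phi = grid, f = v - min(v))
}
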