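# One Monte-Carlo phase of the hybrid scheme: (1) the two half-channel
# glutamates are re-equilibrated with their bulk reservoirs (water in the
# half-channels is assumed to shuttle protons fast enough that aE223/aE162
# stay at local equilibrium); (2) geometry-gated proton transfers are
# attempted between carrier sites. A transfer from donor i to acceptor j is
# possible only if (1) exactly one of the pair is protonated, (2) they are
# close, (3) their side chains are at an appropriate mutual angle, and
# (4) they do not straddle the conserved arginine. Criteria 2-4 enter the
# kinetic weight w = f(r) g(theta) h_arg, and the move is accepted with
#   p = (1 - exp(-k tau w)) * min(1, exp(-dE/kBT)).

#' Kinetic settings of the proton-transfer Monte Carlo
#'
#' @param k_tau Product of the overall transfer rate constant and the time
#'   between MC trials (dimensionless; 1 by convention).
#' @param r0 Distance (Angstrom) below which the distance factor f(r) is 1
#'   (glutamate pairs can approach to ~4 Angstrom).
#' @param lambda Exponential decay length of f(r) beyond `r0`, Angstrom.
#' @param r_max Hard distance cutoff of f(r), Angstrom.
#' @param theta_ref Center (degrees) of the Gaussian side-chain angle factor
#'   g(theta); `NULL` uses the reference angle measured in the geometry
#'   (`geom$theta_ref`).
#' @param sigma Width (degrees) of g(theta).
#' @param max_transfers_per_site Maximum accepted moves a single site may
#'   take part in within one MC phase.
#' @return An object of class `mc_params`.
#' @export
mc_params <- function(k_tau = 1, r0 = 4, lambda = 2.5, r_max = 15,
                      theta_ref = NULL, sigma = 20,
                      max_transfers_per_site = 1L) {
  stopifnot(k_tau > 0, sigma > 0, r_max > r0, lambda > 0,
            max_transfers_per_site >= 1L)
  structure(list(k_tau = k_tau, r0 = r0, lambda = lambda, r_max = r_max,
                 theta_ref = theta_ref, sigma = sigma,
                 max_transfers_per_site = as.integer(max_transfers_per_site)),
            class = "mc_params")
}

#' Mutation flags consumed by the kinetic model
#'
#' @param arg_gate_off If TRUE the arginine leakage gate h is replaced by
#'   unity (arginine-to-alanine mutant).
#' @param delta_r Named numeric vector (by c-subunit letter) of additional
#'   effective transfer distance (Angstrom) contributed by a mutated carrier
#'   (Glu-to-Asp has a shorter side chain).
#' @return A `mutation_flags` list.
#' @export
mutation_flags <- function(arg_gate_off = FALSE, delta_r = numeric(0)) {
  structure(list(arg_gate_off = isTRUE(arg_gate_off), delta_r = delta_r),
            class = "mutation_flags")
}

# distance factor: plateau then exponential decay, hard zero beyond r_max
transfer_f <- function(r, mc) {
  ifelse(r <= mc$r0, 1,
         ifelse(r <= mc$r_max, exp(-(r - mc$r0) / mc$lambda), 0))
}

# Gaussian side-chain angle factor
transfer_g <- function(theta, theta_ref, mc) {
  exp(-(theta - theta_ref)^2 / (2 * mc$sigma^2))
}

#' Kinetic weight of a proton-transfer attempt
#'
#' \eqn{w = f(r)\,g(\theta)\,h_{arg}} with f a plateau-exponential decreasing
#' distance factor, g a Gaussian in the donor/acceptor side-chain angle, and
#' h the arginine gate (0 for straddling pairs in the wild type, 1
#' otherwise, and identically 1 in the arginine-to-alanine mutant).
#'
#' @param r Donor-acceptor distance, Angstrom (effective distance for
#'   mutated carriers).
#' @param theta Angle between donor and acceptor side-chain vectors, degrees.
#' @param straddle Does the pair straddle the conserved arginine?
#' @param mc An [mc_params()].
#' @param flags A [mutation_flags()].
#' @param theta_ref Gaussian center override (degrees); defaults to
#'   `mc$theta_ref`.
#' @return Weight in `[0, 1]`.
#' @export
transfer_weight <- function(r, theta, straddle, mc = mc_params(),
                            flags = mutation_flags(),
                            theta_ref = mc$theta_ref) {
  stopifnot(all(r >= 0))
  if (is.null(theta_ref)) stop("theta_ref is NULL: supply it or set mc$theta_ref")
  h <- ifelse(straddle & !flags$arg_gate_off, 0, 1)
  transfer_f(r, mc) * transfer_g(theta, theta_ref, mc) * h
}

#' Acceptance probability of a proton transfer
#'
#' \eqn{p = (1 - e^{-k\tau w})\,\min(1, e^{-\Delta E/k_BT})}: a kinetic
#' prefactor bounded by the kinetic ceiling \eqn{1 - e^{-k\tau}} times the
#' Metropolis factor for the energy change of the move.
#'
#' @param weight Kinetic weight in `[0, 1]`.
#' @param delta_e Energy change of the transfer, kBT.
#' @param mc An [mc_params()].
#' @return Probability in `[0, 1]`.
#' @export
transfer_probability <- function(weight, delta_e, mc = mc_params()) {
  stopifnot(all(weight >= 0), all(weight <= 1))
  (1 - exp(-mc$k_tau * weight)) * pmin(1, exp(-delta_e))
}

#' Resample the half-channel protonation states from equilibrium
#'
#' Each channel glutamate is redrawn independently: protonated with
#' probability \eqn{P(\epsilon_{site})} from [channel_epsilon()]. c-ring
#' entries are untouched. Consumes two uniform deviates from the R RNG.
#'
#' @param state A [protonation_state()].
#' @param params An [energy_params()].
#' @param geom The `fo_geometry`.
#' @return The updated `protonation_state`.
#' @export
sample_channel_states <- function(state, params, geom) {
  n_c <- geom$n_c
  for (k in c(1L, 2L)) {
    role <- c("channel_ims", "channel_matrix")[k]
    p_prot <- equilibrium_protonation_probability(channel_epsilon(role, params))
    state[n_c + k] <- if (runif(1) < p_prot) 0L else 1L
  }
  state
}

# geometry of all ordered carrier pairs at the current rotation:
# distances, side-chain angles, straddle flags
.pair_geometry <- function(geom, ring) {
  ids <- carrier_ids(geom)
  idx <- match(ids, geom$sites$site_id)
  pos <- stator_positions(geom, ring$phi)[idx, , drop = FALSE]
  dirs <- stator_dirs(geom, ring$phi)[idx, , drop = FALSE]
  az <- stator_azimuths(geom, ring$phi)[idx]
  n <- length(ids)
  d <- as.matrix(dist(pos))
  cosang <- tcrossprod(dirs)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  theta <- rad2deg(acos(cosang))
  strad <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      strad[i, j] <- strad[j, i] <- .straddles_az(az[i], az[j], geom$arg_azimuth)
    }
  }
  list(ids = ids, idx = idx, dist = d, theta = theta, straddle = strad)
}

# per-carrier delta_r from mutation flags (0 for unmutated / channel sites)
.carrier_delta_r <- function(geom, flags) {
  n_c <- geom$n_c
  dr <- numeric(n_c + 2L)
  if (length(flags$delta_r) > 0) {
    k <- match(names(flags$delta_r), letters[seq_len(n_c)])
    if (anyNA(k)) stop("delta_r names unknown subunit: ",
                       paste(names(flags$delta_r)[is.na(k)], collapse = ", "))
    dr[k] <- as.numeric(flags$delta_r)
  }
  dr
}

#' Enumerate transfer-eligible donor/acceptor pairs
#'
#' Ordered pairs (donor protonated, acceptor deprotonated) of carrier sites
#' whose effective distance is within `r_max` and which do not straddle the
#' arginine (unless the gate is disabled by the arginine mutant flag).
#' c-site to c-site pairs are admitted by the same criteria; their
#' near-parallel side chains make the angle factor suppress them in
#' practice.
#'
#' @param state A [protonation_state()].
#' @param geom The `fo_geometry`.
#' @param ring A [ring_state()].
#' @param mc An [mc_params()].
#' @param flags A [mutation_flags()].
#' @return data.frame with columns donor, acceptor (site ids), r, r_eff,
#'   theta, straddle, weight.
#' @export
eligible_pairs <- function(state, geom, ring, mc = mc_params(),
                           flags = mutation_flags()) {
  pg <- .pair_geometry(geom, ring)
  h <- as.integer(state)
  donors <- which(h == 0L)
  acceptors <- which(h == 1L)
  theta_ref <- if (is.null(mc$theta_ref)) geom$theta_ref else mc$theta_ref
  dr <- .carrier_delta_r(geom, flags)
  out <- list()
  for (i in donors) {
    for (j in acceptors) {
      r <- pg$dist[i, j]
      r_eff <- r + dr[i] + dr[j]
      if (r_eff > mc$r_max) next
      strad <- pg$straddle[i, j]
      if (strad && !flags$arg_gate_off) next
      w <- transfer_weight(r_eff, pg$theta[i, j], strad, mc, flags, theta_ref)
      out[[length(out) + 1L]] <- data.frame(
        donor = pg$ids[i], acceptor = pg$ids[j], r = r, r_eff = r_eff,
        theta = pg$theta[i, j], straddle = strad, weight = w)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      r = numeric(0), r_eff = numeric(0), theta = numeric(0),
                      straddle = logical(0), weight = numeric(0)))
  }
  do.call(rbind, out)
}

.empty_events <- function() {
  data.frame(phase_index = integer(0), donor = integer(0),
             acceptor = integer(0), r = numeric(0), theta = numeric(0),
             weight = numeric(0), delta_e = numeric(0),
             accepted = logical(0), leak_flag = logical(0))
}

#' Execute one proton-transfer Monte-Carlo phase
#'
#' Resamples the channel glutamates from their reservoir equilibria, then
#' visits the eligible donor/acceptor pairs in a uniformly random
#' permutation, attempting each once with
#' \eqn{\Delta E = V_{total}(after) - V_{total}(before)} evaluated at the
#' current (possibly already updated) protonation state. A site takes part
#' in at most `mc$max_transfers_per_site` accepted moves per phase. Every
#' attempt is logged.
#'
#' @inheritParams eligible_pairs
#' @param energy An [energy_params()].
#' @param phase_index Integer tag copied into the event log.
#' @return List with elements `state` (updated [protonation_state()]) and
#'   `events` (data.frame of attempts: phase_index, donor, acceptor, r,
#'   theta, weight, delta_e, accepted, leak_flag).
#' @export
mc_phase <- function(state, geom, ring, energy, mc = mc_params(),
                     flags = mutation_flags(), phase_index = 0L) {
  state <- sample_channel_states(state, energy, geom)
  pairs <- eligible_pairs(state, geom, ring, mc, flags)
  if (nrow(pairs) == 0L) return(list(state = state, events = .empty_events()))

  ord <- sample.int(nrow(pairs))
  ids <- attr(state, "carrier_ids")
  n_acc <- integer(length(ids))
  v_before <- .v_state(state, geom, ring, energy)
  ev <- vector("list", nrow(pairs))
  n_ev <- 0L
  for (k in ord) {
    di <- match(pairs$donor[k], ids)
    ai <- match(pairs$acceptor[k], ids)
    # occupancy may have changed earlier in the phase
    if (state[di] != 0L || state[ai] != 1L) next
    if (n_acc[di] >= mc$max_transfers_per_site ||
        n_acc[ai] >= mc$max_transfers_per_site) next
    trial <- state
    trial[di] <- 1L
    trial[ai] <- 0L
    v_after <- .v_state(trial, geom, ring, energy)
    de <- v_after - v_before
    p <- transfer_probability(pairs$weight[k], de, mc)
    acc <- runif(1) < p
    if (acc) {
      state <- trial
      v_before <- v_after
      n_acc[di] <- n_acc[di] + 1L
      n_acc[ai] <- n_acc[ai] + 1L
    }
    n_ev <- n_ev + 1L
    ev[[n_ev]] <- data.frame(
      phase_index = as.integer(phase_index),
      donor = pairs$donor[k], acceptor = pairs$acceptor[k],
      r = pairs$r_eff[k], theta = pairs$theta[k],
      weight = pairs$weight[k], delta_e = de, accepted = acc,
      leak_flag = pairs$straddle[k])
  }
  events <- if (n_ev > 0L) do.call(rbind, ev[seq_len(n_ev)]) else .empty_events()
  list(state = state, events = events)
}
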