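# Mechanical propagation between MC phases. Default mode treats the c-ring
# as a rigid rotor: one overdamped Langevin degree of freedom (the ring
# angle phi) on the angle-dependent part of V_total at fixed protonation.
# Because that potential is a fixed smooth periodic function of phi within
# a segment, the integrator works from a precomputed force table on a fine
# angular grid (linear interpolation between nodes), which makes the inner
# loop cheap without compiled code. Bead mode propagates per-residue
# C-alpha beads under an elastic network.
#
# Reduced time units: one MD segment spans steps_per_segment * dt = 1
# segment-time by default (the original protocol's 1e5 steps correspond to
# dt = 1e-5 in these units; the package default 800 x 0.00125 preserves the
# segment diffusion time at desk scale).

#' Dynamics settings
#'
#' @param mode `"rigid_rotor"` (default) or `"bead"`.
#' @param dt Integrator time step, reduced units.
#' @param steps_per_segment Langevin steps per MD segment (between MC
#'   phases).
#' @param rotational_friction Rotational friction, kBT time/deg^2. The
#'   default `1/648` makes a free ring diffuse 36 deg RMS (one subunit
#'   spacing) per unit segment time, keeping the MC and MD timescales
#'   comparable.
#' @param bead_friction Per-bead friction, kBT time/Angstrom^2 (bead mode).
#' @param kbt Reduced thermal energy scaling the Langevin noise (energies
#'   are already in kBT, so 1 is the physical choice; 0 gives deterministic
#'   gradient descent, useful for locating minima).
#' @param max_step Abort threshold (degrees, or Angstrom in bead mode) for a
#'   single step; exceeding it signals numerical blow-up.
#' @param grid_res Angular resolution (degrees) of the precomputed force
#'   table; must divide 360.
#' @return An object of class `dyn_params`.
#' @export
dyn_params <- function(mode = c("rigid_rotor", "bead"), dt = 0.00125,
                       steps_per_segment = 800L,
                       rotational_friction = 1 / 648,
                       bead_friction = 1, kbt = 1, max_step = 8,
                       grid_res = 0.25) {
  mode <- match.arg(mode)
  stopifnot(dt > 0, steps_per_segment >= 1, rotational_friction > 0,
            bead_friction > 0, kbt >= 0, 360 %% grid_res == 0)
  structure(list(mode = mode, dt = dt,
                 steps_per_segment = as.integer(steps_per_segment),
                 rotational_friction = rotational_friction,
                 bead_friction = bead_friction, kbt = kbt,
                 max_step = max_step, grid_res = grid_res),
            class = "dyn_params")
}

#' Precompute the angle-dependence kernels of the rotor potential
#'
#' For every c-carrier site, tabulates its screened-Coulomb interaction
#' with each (potentially charged) stator site and its lipid-facing weight
#' as functions of the ring angle on a `grid_res`-spaced grid. A segment's
#' potential/force table is then an O(n) sum of these kernels for the
#' currently charged sites ([rotor_force_grid()]), so the Langevin loop
#' never re-evaluates pair distances.
#'
#' @param geom The `fo_geometry`.
#' @param energy An [energy_params()].
#' @param grid_res Grid spacing in degrees (must divide 360).
#' @return A `rotor_field` object (kernels plus grid metadata).
#' @export
make_rotor_field <- function(geom, energy, grid_res = 0.25) {
  stopifnot(360 %% grid_res == 0)
  grid <- seq(0, 360 - grid_res, by = grid_res)
  s <- geom$sites
  ids <- carrier_ids(geom)
  idx <- match(ids, s$site_id)
  is_c <- s$role[idx] == "c_carrier"
  c_idx <- idx[is_c]
  B <- coulomb_prefactor(energy)

  a_roles <- c("arginine", "channel_ims", "channel_matrix")
  a_rows <- lapply(a_roles, function(rl) s[s$role == rl, ])
  names(a_rows) <- a_roles

  K <- vector("list", length(c_idx))
  M <- vector("list", length(c_idx))
  for (kk in seq_along(c_idx)) {
    crow <- s[c_idx[kk], ]
    az_c <- .body_azimuth(crow)
    rc <- sqrt(crow$x^2 + crow$y^2)
    az_stator <- az_c + grid
    Kk <- list()
    for (rl in a_roles) {
      a <- a_rows[[rl]]
      ra <- sqrt(a$x^2 + a$y^2)
      d <- sqrt(rc^2 + ra^2 -
                  2 * rc * ra * cos(deg2rad(az_stator - .body_azimuth(a))) +
                  (crow$z - a$z)^2)
      u <- B * exp(-d / energy$debye_length) / d
      u[d > energy$coulomb_cutoff] <- 0
      Kk[[rl]] <- u
    }
    K[[kk]] <- Kk
    M[[kk]] <- lipid_weight_az(az_stator, geom)
  }
  structure(list(grid_res = grid_res, n_grid = length(grid), K = K, M = M,
                 carrier_ids = ids),
            class = "rotor_field")
}

#' Potential and force tables for one protonation state
#'
#' Assembles V(phi) and F(phi) = -dV/dphi on the field's angular grid for
#' the given protonation state: screened-Coulomb kernels of each
#' deprotonated carrier against the charged stator sites, plus the membrane
#' burial term. Angle-independent contributions (c-c pairs, V_pKa) are
#' omitted; they exert no torque.
#'
#' @param field A [make_rotor_field()] result.
#' @param state A [protonation_state()].
#' @param energy An [energy_params()].
#' @return List with `v` and `f` (numeric vectors over the grid) and
#'   `grid_res`.
#' @export
rotor_force_grid <- function(field, state, energy) {
  n_c <- length(field$K)
  h <- as.integer(state)
  q_a <- c(arginine = energy$charge_arginine,
           channel_ims = -h[n_c + 1L], channel_matrix = -h[n_c + 2L])
  v <- numeric(field$n_grid)
  for (kk in seq_len(n_c)) {
    if (h[kk] != 1L) next
    for (rl in names(q_a)) {
      if (q_a[[rl]] != 0) v <- v + (-1) * q_a[[rl]] * field$K[[kk]][[rl]]
    }
    v <- v + energy$membrane_penalty * field$M[[kk]]
  }
  n <- field$n_grid
  f <- -(v[c(2:n, 1L)] - v[c(n, 1:(n - 1L))]) / (2 * field$grid_res)
  list(v = v, f = f, grid_res = field$grid_res)
}

# Euler-Maruyama on a tabulated periodic force (linear interpolation)
.langevin_grid <- function(phi0, f, grid_res, steps, dt, gamma, kbt,
                           max_step) {
  noise <- if (kbt > 0) rnorm(steps, sd = sqrt(2 * kbt * dt / gamma))
           else numeric(steps)
  if (all(f == 0)) {
    if (steps > 0 && length(noise) > 0 && max(abs(noise)) > max_step) {
      stop("Langevin step exceeded ", max_step, " deg; reduce dt")
    }
    return(sum(noise))
  }
  n <- length(f)
  mob_dt <- dt / gamma
  phi <- phi0
  delta <- 0
  for (t in seq_len(steps)) {
    k <- (phi %% 360) / grid_res
    i0 <- floor(k)
    w <- k - i0
    i0 <- i0 + 1
    i1 <- if (i0 == n) 1L else i0 + 1L
    dphi <- (f[i0] * (1 - w) + f[i1] * w) * mob_dt + noise[t]
    if (abs(dphi) > max_step) {
      stop("Langevin step exceeded ", max_step, " deg; reduce dt")
    }
    phi <- phi + dphi
    delta <- delta + dphi
  }
  delta
}

#' Torque on the rigid c-ring
#'
#' \eqn{-dV_{total}/d\phi} by central finite difference of the
#' protonation-dependent potential (the structure-maintaining term is
#' angle-independent for a rigid rotor).
#'
#' @param phi Ring angle, degrees.
#' @param state A [protonation_state()].
#' @param geom The `fo_geometry`.
#' @param energy An [energy_params()].
#' @param dphi Finite-difference step, degrees.
#' @return Torque in kBT/deg.
#' @export
torque <- function(phi, state, geom, energy, dphi = 0.01) {
  vp <- .v_state(state, geom, ring_state(phi + dphi), energy)
  vm <- .v_state(state, geom, ring_state(phi - dphi), energy)
  -(vp - vm) / (2 * dphi)
}

#' Advance the mechanics by one MD segment
#'
#' Rigid-rotor mode: `steps_per_segment` Euler-Maruyama updates
#' \eqn{d\phi = (\tau/\gamma)dt + \sqrt{2 k_BT dt/\gamma}\,N(0,1)} on the
#' angle-dependent potential at fixed protonation, with `phi_cumulative`
#' unwrapped continuously. Bead mode: per-bead overdamped Langevin under the
#' elastic network, with the ring angle updated by the best-fit rotation of
#' the beads about the axis. The protonation state is untouched.
#'
#' @param ring A [ring_state()].
#' @inheritParams torque
#' @param dyn A [dyn_params()].
#' @param field Optional precomputed [make_rotor_field()] (built on the fly
#'   otherwise; precompute it when calling in a loop).
#' @param network Elastic network (bead mode only).
#' @return The advanced `ring_state`.
#' @export
md_segment <- function(ring, state, geom, energy, dyn = dyn_params(),
                       field = NULL, network = NULL) {
  if (dyn$mode == "rigid_rotor") {
    if (is.null(field)) field <- make_rotor_field(geom, energy, dyn$grid_res)
    fg <- rotor_force_grid(field, state, energy)
    delta <- .langevin_grid(ring$phi, fg$f, fg$grid_res,
                            dyn$steps_per_segment, dyn$dt,
                            dyn$rotational_friction, dyn$kbt, dyn$max_step)
    ring_state(phi = ring$phi + delta,
               phi_cumulative = ring$phi_cumulative + delta)
  } else {
    if (is.null(network) || is.null(ring$bead_coords)) {
      stop("bead mode requires an elastic network and ring$bead_coords")
    }
    x <- ring$bead_coords
    noise_sd <- sqrt(2 * dyn$kbt * dyn$dt / dyn$bead_friction)
    for (t in seq_len(dyn$steps_per_segment)) {
      ff <- elastic_network_forces(x, network)
      dx <- ff / dyn$bead_friction * dyn$dt
      if (noise_sd > 0) dx <- dx + noise_sd * matrix(rnorm(length(x)), nrow(x), 3)
      if (max(abs(dx)) > dyn$max_step) {
        stop("Langevin step exceeded ", dyn$max_step, " A; reduce dt")
      }
      x <- x + dx
    }
    dphi <- .fit_axis_rotation(ring$bead_coords, x)
    out <- ring_state(phi = ring$phi + dphi,
                      phi_cumulative = ring$phi_cumulative + dphi)
    out$bead_coords <- x
    out
  }
}

# best-fit rotation about +z between two coordinate sets (degrees)
.fit_axis_rotation <- function(ref, cur) {
  num <- sum(ref[, 1] * cur[, 2] - ref[, 2] * cur[, 1])
  den <- sum(ref[, 1] * cur[, 1] + ref[, 2] * cur[, 2])
  rad2deg(atan2(num, den))
}

#' Reference overdamped Langevin integrator on an arbitrary 1-D potential
#'
#' Plain Euler-Maruyama propagation of a single angular coordinate on a
#' user-supplied potential (kBT units), with the force from a central
#' finite difference at every step. The slow, transparent counterpart of
#' the tabulated-force path in [md_segment()]; used in tests and
#' illustrations.
#'
#' @param phi0 Initial angle, degrees.
#' @param potential Function of one angle (degrees) returning energy (kBT).
#' @param gamma Friction, kBT time/deg^2.
#' @param dt Time step.
#' @param steps Number of steps.
#' @param kbt Reduced thermal energy (0 = gradient descent).
#' @param record_every Thinning interval of the returned samples.
#' @param dphi Finite-difference step for the force, degrees.
#' @return Numeric vector of recorded angles (unwrapped).
#' @export
langevin_rotor <- function(phi0, potential, gamma, dt, steps, kbt = 1,
                           record_every = 1L, dphi = 0.01) {
  phi <- phi0
  noise_sd <- sqrt(2 * kbt * dt / gamma)
  out <- numeric(steps %/% record_every)
  j <- 0L
  for (t in seq_len(steps)) {
    f <- -(potential(phi + dphi) - potential(phi - dphi)) / (2 * dphi)
    phi <- phi + f / gamma * dt + if (noise_sd > 0) noise_sd * rnorm(1) else 0
    if (t %% record_every == 0L) {
      j <- j + 1L
      out[j] <- phi
    }
  }
  out
}

#' Build an elastic network from reference coordinates
#'
#' Harmonic restraints between all bead pairs within `cutoff` in the
#' reference (native) structure; the structure-maintaining stand-in for the
#' non-electrostatic term in bead mode.
#'
#' @param coords Reference coordinate matrix (n x 3), Angstrom.
#' @param cutoff Native-contact distance cutoff, Angstrom.
#' @param k Spring constant, kBT/Angstrom^2.
#' @return An `elastic_network` list with the pair list, native distances
#'   and spring constant.
#' @export
build_elastic_network <- function(coords, cutoff = 10, k = 1) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  d <- as.matrix(dist(coords))
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  structure(list(i = pairs[, 1], j = pairs[, 2],
                 r0 = d[pairs], k = k, ref = coords),
            class = "elastic_network")
}

#' Elastic-network energy
#'
#' @param coords Coordinate matrix (n x 3).
#' @param network A [build_elastic_network()] result.
#' @return Energy in kBT; 0 at the native structure.
#' @export
elastic_energy <- function(coords, network) {
  dx <- coords[network$i, , drop = FALSE] - coords[network$j, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  0.5 * network$k * sum((r - network$r0)^2)
}

#' Elastic-network forces
#'
#' Harmonic pair forces \eqn{-k(r - r_0)\hat{r}} on each bead; the exact
#' negative gradient of [elastic_energy()].
#'
#' @inheritParams elastic_energy
#' @return Force matrix (n x 3), kBT/Angstrom.
#' @export
elastic_network_forces <- function(coords, network) {
  f <- matrix(0, nrow(coords), 3)
  dx <- coords[network$i, , drop = FALSE] - coords[network$j, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  mag <- -network$k * (r - network$r0) / r
  fij <- dx * mag
  agg <- rowsum(rbind(fij, -fij), group = c(network$i, network$j))
  f[as.integer(rownames(agg)), ] <- agg
  f
}
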