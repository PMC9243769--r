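# Orchestration of the hybrid scheme: alternate proton-transfer MC phases
# with Langevin MD segments, under one seeded RNG, with mutation models and
# per-phase trajectory records.

#' Specify a mutation
#'
#' Two mutant classes are modelled. `arginine_to_ala` disables the
#' arginine leakage gate: the factor h is replaced by unity, so transfers
#' across the arginine azimuth become possible (this is the literal mutant
#' model; set `drop_charge = TRUE` to additionally delete the +1 charge for
#' a full physical ablation). `carrier_e_to_d` mutates the carrier
#' glutamate of the named c-subunits to aspartate: a shorter side chain
#' (`delta_r` added to the effective transfer distance) with a lower
#' intrinsic pKa (`delta_pka`).
#'
#' @param kind `"arginine_to_ala"` or `"carrier_e_to_d"`.
#' @param target_subunits Subunit letters (a, b, ...) for carrier mutations.
#' @param delta_pka pKa shift (pH units) of the mutated carrier.
#' @param delta_r Added effective transfer distance (Angstrom) of the
#'   mutated carrier.
#' @param drop_charge Also remove the arginine +1 charge
#'   (`arginine_to_ala` only).
#' @return A `mutation_spec` object.
#' @export
mutation_spec <- function(kind = c("arginine_to_ala", "carrier_e_to_d"),
                          target_subunits = NULL, delta_pka = -1.0,
                          delta_r = 1.5, drop_charge = FALSE) {
  kind <- match.arg(kind)
  if (kind == "carrier_e_to_d" && length(target_subunits) == 0) {
    stop("carrier_e_to_d requires target_subunits")
  }
  structure(list(kind = kind, target_subunits = target_subunits,
                 delta_pka = delta_pka, delta_r = delta_r,
                 drop_charge = isTRUE(drop_charge)),
            class = "mutation_spec")
}

#' Apply mutation specs to the energy model and kinetic flags
#'
#' @param geom The `fo_geometry`.
#' @param energy An [energy_params()].
#' @param mutations List of [mutation_spec()] objects.
#' @return List with elements `energy` (possibly modified) and `flags`
#'   (a [mutation_flags()]).
#' @export
apply_mutations <- function(geom, energy, mutations = list()) {
  flags <- mutation_flags()
  if (length(mutations) == 0) return(list(energy = energy, flags = flags))
  labs <- letters[seq_len(geom$n_c)]
  n_arg <- 0L
  for (m in mutations) {
    stopifnot(inherits(m, "mutation_spec"))
    if (m$kind == "arginine_to_ala") {
      n_arg <- n_arg + 1L
      if (n_arg > 1L) stop("at most one arginine mutation")
      flags$arg_gate_off <- TRUE
      if (m$drop_charge) energy$charge_arginine <- 0
    } else {
      bad <- setdiff(m$target_subunits, labs)
      if (length(bad) > 0) stop("unknown subunit label(s): ",
                                paste(bad, collapse = ", "))
      ov <- if (is.null(energy$pKa_overrides)) numeric(0) else energy$pKa_overrides
      for (su in m$target_subunits) {
        ov[su] <- energy$pKa$cE59 + m$delta_pka
        flags$delta_r[su] <- m$delta_r
      }
      energy$pKa_overrides <- ov
    }
  }
  list(energy = energy, flags = flags)
}

#' Assemble a full simulation configuration
#'
#' @param geometry Either an `fo_geometry` or a list of arguments for
#'   [build_synthetic_geometry()].
#' @param energy An [energy_params()].
#' @param mc An [mc_params()].
#' @param dyn A [dyn_params()].
#' @param n_phases Total number of MC/MD phases.
#' @param burn_in Phases discarded by the summary statistics
#'   (`0 <= burn_in <= n_phases`).
#' @param mutations List of [mutation_spec()] objects.
#' @param seed Integer RNG seed; all randomness (MC and Langevin noise)
#'   derives from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(geometry = list(), energy = energy_params(),
                       mc = mc_params(), dyn = dyn_params(),
                       n_phases = 2000L, burn_in = 200L,
                       mutations = list(), seed = 1L) {
  stopifnot(n_phases >= 0, burn_in >= 0, n_phases >= burn_in)
  structure(list(geometry = geometry, energy = energy, mc = mc, dyn = dyn,
                 n_phases = as.integer(n_phases), burn_in = as.integer(burn_in),
                 mutations = mutations, seed = as.integer(seed)),
            class = "sim_config")
}

.resolve_geometry <- function(geometry) {
  if (inherits(geometry, "fo_geometry")) geometry
  else do.call(build_synthetic_geometry, geometry)
}

#' Run a hybrid MC/MD simulation
#'
#' For each phase: one proton-transfer MC phase ([mc_phase()]) followed by
#' one Langevin MD segment ([md_segment()]). Fully deterministic for a fixed
#' config and seed. The initial state is the fully protonated ring at
#' phi = 0 with the channel glutamates drawn from their equilibria.
#'
#' @param config A [sim_config()].
#' @return An `fo_trajectory`: list with `phases` (one row per phase: phi,
#'   phi_cumulative, protonation string, deprotonated-carrier count, energy
#'   breakdown, accepted-event count), `events` (the full transfer-attempt
#'   log), plus the resolved `geom`, mutated `energy`, `flags` and `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  geom <- .resolve_geometry(config$geometry)
  mut <- apply_mutations(geom, config$energy, config$mutations)
  energy <- mut$energy
  flags <- mut$flags

  n <- config$n_phases
  state <- protonation_state(geom)
  ring <- ring_state(0)
  field <- make_rotor_field(geom, energy, config$dyn$grid_res)
  phases <- data.frame(
    phase = integer(n), phi = numeric(n), phi_cumulative = numeric(n),
    h = character(n), n_dep_c = integer(n),
    v_coulomb = numeric(n), v_membrane = numeric(n), v_pka = numeric(n),
    v_total = numeric(n), n_accepted = integer(n),
    stringsAsFactors = FALSE)
  ev_list <- vector("list", n)

  for (p in seq_len(n)) {
    step <- mc_phase(state, geom, ring, energy, config$mc, flags,
                     phase_index = p)
    state <- step$state
    if (nrow(step$events) > 0L) ev_list[[p]] <- step$events
    ring <- md_segment(ring, state, geom, energy, config$dyn, field = field)
    eb <- v_total(state, geom, ring, energy)
    phases$phase[p] <- p
    phases$phi[p] <- ring$phi
    phases$phi_cumulative[p] <- ring$phi_cumulative
    phases$h[p] <- paste(as.integer(state), collapse = "")
    phases$n_dep_c[p] <- sum(as.integer(state)[seq_len(geom$n_c)])
    phases$v_coulomb[p] <- eb$v_coulomb
    phases$v_membrane[p] <- eb$v_membrane
    phases$v_pka[p] <- eb$v_pka
    phases$v_total[p] <- eb$v_total
    phases$n_accepted[p] <- sum(step$events$accepted)
  }
  events <- ev_list[!vapply(ev_list, is.null, logical(1))]
  events <- if (length(events) > 0L) do.call(rbind, events) else .empty_events()
  rownames(events) <- NULL
  structure(list(phases = phases, events = events, geom = geom,
                 energy = energy, flags = flags, config = config),
            class = "fo_trajectory")
}

#' @export
print.fo_trajectory <- function(x, ...) {
  n <- nrow(x$phases)
  cat("fo_trajectory:", n, "phases, seed", x$config$seed, "\n")
  if (n > 0) {
    cat(sprintf("  cumulative rotation %.1f deg; %d accepted transfers\n",
                x$phases$phi_cumulative[n], sum(x$events$accepted)))
  }
  invisible(x)
}

#' Mean rotational velocity of a trajectory
#'
#' Cumulative rotation gained after burn-in divided by the number of
#' post-burn-in phases.
#'
#' @param traj An `fo_trajectory`.
#' @param burn_in Phases to discard; defaults to the config value.
#' @return Velocity in degrees per MC phase.
#' @export
mean_velocity <- function(traj, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- traj$config$burn_in
  ph <- traj$phases
  n <- nrow(ph)
  if (n <= burn_in) stop("trajectory not longer than burn_in")
  start <- if (burn_in == 0) 0 else ph$phi_cumulative[burn_in]
  (ph$phi_cumulative[n] - start) / (n - burn_in)
}

#' Scan carrier Glu-to-Asp mutants at increasing spacing
#'
#' Runs the wild type, the single mutant and the requested double mutants
#' (subunit-pair strings such as `"ef"`) across several seeds and reports
#' the mean rotational velocity with its standard error — the simulation
#' counterpart of comparing mutant ATP-synthesis activities.
#'
#' @param base_config A [sim_config()] (its `mutations` are replaced per
#'   variant).
#' @param variants Character vector of variants: `"wt"`, a single subunit
#'   letter, or a pair of letters; duplicates are dropped with a warning.
#' @param seeds Integer seeds (>= 2 for a standard error).
#' @param delta_pka,delta_r Mutation magnitudes passed to [mutation_spec()].
#' @return data.frame with variant, n_seeds, mean_velocity (deg/phase), se.
#' @export
mutant_scan <- function(base_config,
                        variants = c("wt", "e", "ef", "eg", "eh", "ei", "ej"),
                        seeds = 1:5, delta_pka = -1.0, delta_r = 1.5) {
  if (anyDuplicated(variants)) {
    warning("duplicate variants dropped: ",
            paste(unique(variants[duplicated(variants)]), collapse = ", "))
    variants <- unique(variants)
  }
  rows <- vector("list", length(variants))
  for (vi in seq_along(variants)) {
    v <- variants[vi]
    muts <- if (identical(v, "wt")) list() else {
      list(mutation_spec("carrier_e_to_d",
                         target_subunits = strsplit(v, "")[[1]],
                         delta_pka = delta_pka, delta_r = delta_r))
    }
    vel <- vapply(seeds, function(s) {
      cfg <- base_config
      cfg$mutations <- muts
      cfg$seed <- as.integer(s)
      mean_velocity(run_simulation(cfg))
    }, numeric(1))
    rows[[vi]] <- data.frame(variant = v, n_seeds = length(seeds),
                             mean_velocity = mean(vel),
                             se = sd(vel) / sqrt(length(vel)))
  }
  do.call(rbind, rows)
}

#' Sample ring angles at a fixed protonation state
#'
#' Runs MD segments with the Monte Carlo disabled (fixed protonation
#' vector), recording the ring angle after every segment. Used to build
#' per-state free-energy surfaces along the rotary angle and the
#' cross-evaluated energies consumed by the Bennett acceptance ratio
#' estimator.
#'
#' @param geom The `fo_geometry`.
#' @param h Protonation vector (length `n_c + 2`) held fixed.
#' @param energy An [energy_params()].
#' @param dyn A [dyn_params()].
#' @param n_segments Number of MD segments (one recorded angle each).
#' @param phi0 Initial angle, degrees.
#' @param seed Optional seed (`NULL` leaves the RNG stream untouched).
#' @return Numeric vector of `n_segments` angles (degrees, wrapped).
#' @export
sample_angles_fixed_h <- function(geom, h, energy = energy_params(),
                                  dyn = dyn_params(), n_segments = 1000L,
                                  phi0 = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- protonation_state(geom, h)
  ring <- ring_state(phi0)
  field <- make_rotor_field(geom, energy, dyn$grid_res)
  out <- numeric(n_segments)
  for (k in seq_len(n_segments)) {
    ring <- md_segment(ring, state, geom, energy, dyn, field = field)
    out[k] <- ring$phi
  }
  out
}
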