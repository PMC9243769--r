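# Shared fixtures: all built in code at test time.

# short simulation config with standard driving conditions
test_config <- function(n_phases = 300, burn_in = 50, seed = 1, ...) {
  sim_config(n_phases = n_phases, burn_in = burn_in, seed = seed, ...)
}

# minimal C-alpha-only PDB text for a synthetic Fo: n_c carrier glutamates
# on a ring (chains as given), plus the a-subunit channel/arginine residues.
# `transform` optionally rotates/translates all coordinates to exercise the
# ring-axis fit.
write_synthetic_pdb <- function(path, n_c = 10, radius = 25,
                                c_chains = LETTERS[3:(2 + n_c)],
                                a_chain = "A",
                                carrier_resno = 59,
                                channel_ims = 223, channel_matrix = 162,
                                arginine = 176,
                                channel_offsets = c(25, -25),
                                drop_chain = NULL,
                                transform = identity) {
  deg <- pi / 180
  rows <- character(0)
  serial <- 0L
  emit <- function(resname, chain, resno, xyz) {
    serial <<- serial + 1L
    xyz <- transform(xyz)
    sprintf("ATOM  %5d  CA  %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, resname, chain, resno, xyz[1], xyz[2], xyz[3])
  }
  for (k in seq_len(n_c)) {
    if (!is.null(drop_chain) && c_chains[k] == drop_chain) next
    az <- (k - 1) * 360 / n_c * deg
    rows <- c(rows, emit("GLU", c_chains[k], carrier_resno,
                         c(radius * cos(az), radius * sin(az), 0)))
  }
  a_site <- function(resname, resno, az_deg, r) {
    emit(resname, a_chain, resno,
         c(r * cos(az_deg * deg), r * sin(az_deg * deg), 0))
  }
  rows <- c(rows,
            a_site("GLU", channel_ims, channel_offsets[1], radius + 3),
            a_site("GLU", channel_matrix, channel_offsets[2], radius + 3),
            a_site("ARG", arginine, 0, radius + 6),
            "END")
  writeLines(rows, path)
  invisible(path)
}

default_chain_map <- function(n_c = 10) {
  list(c_chains = LETTERS[3:(2 + n_c)], a_chain = "A")
}

default_carriers <- function() {
  list(c_carrier = 59, channel_ims = 223, channel_matrix = 162,
       arginine = 176)
}

# post-burn-in cumulative rotation and net matrix flux of a trajectory
rot_and_flux <- function(traj) {
  burn <- traj$config$burn_in
  ph <- traj$phases
  ev <- traj$events[traj$events$phase_index > burn, ]
  start <- if (burn == 0) 0 else ph$phi_cumulative[burn]
  c(rot = ph$phi_cumulative[nrow(ph)] - start,
    flux = as.numeric(net_flux(ev, traj$geom)))
}
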