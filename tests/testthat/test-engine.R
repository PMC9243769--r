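test_that("mutation specs modify only what they should", {
  g <- build_synthetic_geometry()
  en <- energy_params()
  # identity
  out <- apply_mutations(g, en, list())
  expect_identical(out$energy, en)
  expect_false(out$flags$arg_gate_off)
  # arginine mutant: gate off, charge kept (literal mutant model)
  out <- apply_mutations(g, en, list(mutation_spec("arginine_to_ala")))
  expect_true(out$flags$arg_gate_off)
  expect_equal(out$energy$charge_arginine, 1)
  # optional full ablation also removes the +1 charge
  out <- apply_mutations(g, en, list(mutation_spec("arginine_to_ala",
                                                   drop_charge = TRUE)))
  expect_equal(out$energy$charge_arginine, 0)
  # carrier mutation changes the named subunit's pKa only
  out <- apply_mutations(g, en, list(
    mutation_spec("carrier_e_to_d", target_subunits = "e", delta_pka = -1)))
  pk <- fomotor:::site_pkas(out$energy, g)
  expect_equal(pk[5], 7.0)
  expect_equal(pk[-5], c(rep(8, 9), 6, 9))
  expect_equal(out$flags$delta_r, c(e = 1.5))
  # errors
  expect_error(apply_mutations(g, en, list(
    mutation_spec("carrier_e_to_d", target_subunits = "q"))), "unknown subunit")
  expect_error(apply_mutations(g, en, list(mutation_spec("arginine_to_ala"),
                                           mutation_spec("arginine_to_ala"))),
               "at most one")
  expect_error(mutation_spec("carrier_e_to_d"), "target_subunits")
})

test_that("an empty run returns an empty trajectory without error", {
  traj <- run_simulation(test_config(n_phases = 0, burn_in = 0))
  expect_equal(nrow(traj$phases), 0L)
  expect_equal(nrow(traj$events), 0L)
})

test_that("runs are reproducible and trajectory files byte-identical", {
  cfg <- test_config(n_phases = 120, burn_in = 20, seed = 14)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$phases, t2$phases)
  expect_identical(t1$events, t2$events)
  d1 <- tempfile(); d2 <- tempfile()
  write_trajectory(t1, d1)
  write_trajectory(t2, d2)
  for (f in c("phases.tsv", "events.tsv", "geometry.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # and a different seed changes the outcome
  cfg$seed <- 15L
  t3 <- run_simulation(cfg)
  expect_false(identical(t1$phases$phi, t3$phases$phi))
})

test_that("trajectory records are internally consistent", {
  traj <- run_simulation(test_config(n_phases = 150, burn_in = 0, seed = 2))
  ph <- traj$phases
  expect_equal(nrow(ph), 150L)
  expect_equal(ph$phase, 1:150)
  # wrapped and cumulative angles agree modulo 360
  expect_true(all(abs(fomotor:::wrap180(ph$phi_cumulative - ph$phi)) < 1e-9))
  # energy bookkeeping column-wise
  expect_equal(ph$v_total, ph$v_coulomb + ph$v_membrane + ph$v_pka,
               tolerance = 1e-9)
  # deprotonation counts match the recorded state strings
  n_dep <- vapply(strsplit(ph$h, ""), function(x) sum(x[1:10] == "1"),
                  numeric(1))
  expect_equal(ph$n_dep_c, as.integer(n_dep))
  # accepted-event counts match the event log
  by_phase <- table(factor(traj$events$phase_index[traj$events$accepted],
                           levels = 1:150))
  expect_equal(ph$n_accepted, as.integer(by_phase))
})

test_that("mean velocity uses post-burn-in rotation", {
  traj <- run_simulation(test_config(n_phases = 100, burn_in = 20, seed = 6))
  ph <- traj$phases
  v <- mean_velocity(traj)
  expect_equal(v, (ph$phi_cumulative[100] - ph$phi_cumulative[20]) / 80)
  expect_error(mean_velocity(traj, burn_in = 100), "longer than burn_in")
})

test_that("mutant_scan deduplicates variants and returns a tidy table", {
  cfg <- test_config(n_phases = 60, burn_in = 10)
  expect_warning(
    sc <- mutant_scan(cfg, variants = c("wt", "e", "e"), seeds = 1:2),
    "duplicate")
  expect_equal(sc$variant, c("wt", "e"))
  expect_equal(sc$n_seeds, c(2L, 2L))
  expect_true(all(is.finite(sc$mean_velocity)))
  expect_true(all(sc$se >= 0))
})

test_that("YAML configs round-trip through the constructors", {
  # parameters chosen exactly representable at the YAML writer precision
  cfg <- sim_config(geometry = list(n_c = 10, ring_radius = 24),
                    energy = energy_params(pH_matrix = 8.5),
                    mc = mc_params(sigma = 25),
                    dyn = dyn_params(steps_per_segment = 200,
                                     rotational_friction = 1 / 512),
                    n_phases = 44, burn_in = 4, seed = 9,
                    mutations = list(mutation_spec("carrier_e_to_d",
                                                   target_subunits = c("e", "f"))))
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$energy$pH_matrix, 8.5)
  expect_equal(cfg2$mc$sigma, 25)
  expect_equal(cfg2$dyn$steps_per_segment, 200L)
  expect_equal(cfg2$n_phases, 44L)
  expect_equal(cfg2$mutations[[1]]$target_subunits, c("e", "f"))
  expect_equal(cfg2$geometry$ring_radius, 24)
  # identical runs from the original and round-tripped configs
  expect_identical(run_simulation(cfg)$phases, run_simulation(cfg2)$phases)
})

test_that("trajectories round-trip through TSV for analysis", {
  traj <- run_simulation(test_config(n_phases = 130, burn_in = 30, seed = 4))
  dir <- tempfile()
  write_trajectory(traj, dir)
  back <- read_trajectory(dir)
  expect_equal(back$phases$phi_cumulative, traj$phases$phi_cumulative,
               tolerance = 1e-6)  # files carry 10 significant digits
  expect_identical(back$phases$h, traj$phases$h)
  expect_equal(nrow(back$events), nrow(traj$events))
  # the restored object feeds the analysis layer
  expect_equal(deprotonation_count_stats(back)$histogram,
               deprotonation_count_stats(traj)$histogram)
  expect_equal(as.numeric(net_flux(back$events, back$geom)),
               as.numeric(net_flux(traj$events, traj$geom)))
})
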