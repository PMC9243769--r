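geom <- build_synthetic_geometry()
en <- energy_params()
mc <- mc_params()

test_that("the kinetic weight implements f(r) g(theta) h", {
  # straddling pair in the wild type is gated to zero
  expect_equal(transfer_weight(4, 162, TRUE, mc, theta_ref = 162), 0)
  # same pair with the arginine gate disabled
  expect_gt(transfer_weight(4, 162, TRUE, mc,
                            flags = mutation_flags(arg_gate_off = TRUE),
                            theta_ref = 162), 0.99)
  # plateau distance at the reference angle: maximal weight
  expect_equal(transfer_weight(mc$r0, 162, FALSE, mc, theta_ref = 162), 1)
  # beyond the hard cutoff: zero
  expect_equal(transfer_weight(mc$r_max + 0.001, 162, FALSE, mc,
                               theta_ref = 162), 0)
  # f is non-increasing on an r grid
  r <- seq(0, 20, by = 0.05)
  w <- transfer_weight(r, 162, FALSE, mc, theta_ref = 162)
  expect_true(all(diff(w) <= 1e-12))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("transfer probability is the kinetic prefactor times Metropolis", {
  m1 <- mc_params(k_tau = 1)
  expect_equal(transfer_probability(1, 0, m1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(transfer_probability(1, 0, m1), 0.632, tolerance = 1e-3)
  expect_equal(transfer_probability(0, -100, m1), 0)
  expect_equal(transfer_probability(1, 2, m1), (1 - exp(-1)) * exp(-2),
               tolerance = 1e-12)
  expect_equal(transfer_probability(1, 2, m1), 0.0856, tolerance = 1e-3)
  # kinetic ceiling 1 - exp(-k tau) for any energy change
  de <- seq(-10, 10, by = 0.5)
  w <- runif(length(de))
  expect_true(all(transfer_probability(w, de, m1) <= 1 - exp(-1) + 1e-12))
})

test_that("channel resampling matches the equilibrium sigmoid", {
  # matrix channel at standard conditions: epsilon = +0.599, P = 0.354
  set.seed(11)
  st <- protonation_state(geom)
  n <- 30000
  prot <- logical(n)
  for (i in seq_len(n)) {
    st2 <- sample_channel_states(st, en, geom)
    prot[i] <- st2[geom$n_c + 2L] == 0L
  }
  p_expected <- 1 / (1 + exp(0.5990))  # hand value of P(+0.599)
  expect_equal(mean(prot), p_expected, tolerance = 0.01)
  # c-site entries are never touched
  expect_equal(as.integer(st2)[1:10], rep(0L, 10))
})

test_that("eligible pairs honor occupancy, distance and the arginine gate", {
  ring <- ring_state(0)
  # fully protonated: no acceptor, empty list
  expect_equal(nrow(eligible_pairs(protonation_state(geom), geom, ring, mc)), 0L)
  # deprotonated carrier parked just past the arginine (matrix side):
  # uptake from the IMS channel would straddle the gate
  ring2 <- ring_state(-2)  # subunit a at azimuth -2
  st <- protonation_state(geom, c(1L, rep(0L, 9), 0L, 0L))
  ep_wt <- eligible_pairs(st, geom, ring2, mc)
  ims <- geom$sites$site_id[geom$sites$role == "channel_ims"]
  expect_false(any(ep_wt$donor == ims & ep_wt$acceptor == 1))
  ep_mut <- eligible_pairs(st, geom, ring2, mc,
                           mutation_flags(arg_gate_off = TRUE))
  hit <- ep_mut[ep_mut$donor == ims & ep_mut$acceptor == 1, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$straddle)
  expect_gt(hit$weight, 0)
})

test_that("carrier delta_r extends the effective transfer distance", {
  ring <- ring_state(25)  # subunit a at the IMS channel azimuth
  st <- protonation_state(geom, c(1L, rep(0L, 9), 0L, 0L))
  ep0 <- eligible_pairs(st, geom, ring, mc)
  epd <- eligible_pairs(st, geom, ring, mc,
                        mutation_flags(delta_r = c(a = 1.5)))
  ims <- geom$sites$site_id[geom$sites$role == "channel_ims"]
  r0 <- ep0$r_eff[ep0$donor == ims & ep0$acceptor == 1]
  rd <- epd$r_eff[epd$donor == ims & epd$acceptor == 1]
  expect_equal(rd - r0, 1.5, tolerance = 1e-9)
  expect_error(eligible_pairs(st, geom, ring, mc,
                              mutation_flags(delta_r = c(zz = 1))),
               "unknown subunit")
})

test_that("an MC phase conserves protons move-by-move and logs attempts", {
  set.seed(3)
  ring <- ring_state(25)
  st <- protonation_state(geom, c(0L, 1L, rep(0L, 8), 0L, 1L))
  prev_h <- as.integer(st)
  out <- mc_phase(st, geom, ring, en, mc, phase_index = 7L)
  ev <- out$events
  if (nrow(ev) > 0) {
    expect_true(all(ev$phase_index == 7L))
    expect_true(all(ev$weight >= 0 & ev$weight <= 1))
  }
  # replay the accepted events from the pre-phase state (channel resampling
  # affects channels only): each flips donor 0->1 and acceptor 1->0
  ids <- attr(st, "carrier_ids")
  h <- as.integer(out$state)
  c_before <- prev_h[1:10]
  c_after <- h[1:10]
  acc <- ev[ev$accepted, , drop = FALSE]
  delta <- c_after - c_before
  ups <- sum(delta == 1)   # carriers that lost a proton
  downs <- sum(delta == -1)
  c_ids <- ids[1:10]
  expect_equal(ups, sum(acc$donor %in% c_ids))
  expect_equal(downs, sum(acc$acceptor %in% c_ids))
})

test_that("wild-type phases never accept straddling transfers", {
  set.seed(5)
  ring <- ring_state(0)
  st <- protonation_state(geom, c(1L, 0L, rep(0L, 8), 0L, 1L))
  for (i in 1:100) {
    out <- mc_phase(st, geom, ring, en, mc, phase_index = i)
    ev <- out$events
    expect_false(any(ev$accepted & ev$leak_flag))
    st <- out$state
    ring <- ring_state(runif(1, -10, 10))
  }
})

test_that("identical seeds give identical MC phases", {
  ring <- ring_state(20)
  st <- protonation_state(geom, c(1L, rep(0L, 11)))
  set.seed(99); a <- mc_phase(st, geom, ring, en, mc)
  set.seed(99); b <- mc_phase(st, geom, ring, en, mc)
  expect_identical(a, b)
})
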