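geom <- build_synthetic_geometry()

# a hand-built trajectory: 12 phases of scripted angles and protonation
# strings for subunit "a" (body azimuth 0, so phi is its stator azimuth)
make_scripted_traj <- function() {
  phi <- c(100, 100, -30, -30, -30, 0, 20, 25, 25, 60, 100, 100)
  h_a <- c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0)
  h <- vapply(h_a, function(x) paste(c(x, rep(0, 11)), collapse = ""),
              character(1))
  phases <- data.frame(phase = 1:12, phi = fomotor:::wrap360(phi),
                       phi_cumulative = phi, h = h,
                       n_dep_c = h_a, stringsAsFactors = FALSE)
  structure(list(phases = phases, events = fomotor:::.empty_events(),
                 geom = geom,
                 config = list(burn_in = 0L, mc = list(r_max = 15))),
            class = "fo_trajectory")
}

test_that("deprotonation count statistics report histogram and mode", {
  traj <- make_scripted_traj()
  # all-protonated phases dominate this fixture
  st <- deprotonation_count_stats(traj, burn_in = 0)
  expect_equal(sum(st$histogram), 12)
  expect_equal(st$mode, 0L)
  # hand-built counts (2, 2, 3) -> mode 2
  t2 <- traj
  t2$phases <- traj$phases[1:3, ]
  t2$phases$h <- c(paste(c(1, 1, rep(0, 10)), collapse = ""),
                   paste(c(1, 1, rep(0, 10)), collapse = ""),
                   paste(c(1, 1, 1, rep(0, 9)), collapse = ""))
  t2$phases$n_dep_c <- c(2L, 2L, 3L)
  st2 <- deprotonation_count_stats(t2, burn_in = 0)
  expect_equal(st2$mode, 2L)
  expect_false(st2$tie)
  # ties are flagged
  t3 <- t2
  t3$phases <- t3$phases[1:2, ]
  t3$phases$n_dep_c <- c(1L, 2L)
  st3 <- deprotonation_count_stats(t3, burn_in = 0)
  expect_true(st3$tie)
})

test_that("DEP-state labels name the deprotonated subunits", {
  t2 <- make_scripted_traj()
  t2$phases <- t2$phases[1:2, ]
  t2$phases$h <- c(paste(c(1, 1, rep(0, 10)), collapse = ""),
                   paste(rep(0, 12), collapse = ""))
  expect_equal(dep_state_labels(t2, burn_in = 0), c("a+b", ""))
})

test_that("net flux counts matrix deliveries by definition", {
  ims <- geom$sites$site_id[geom$sites$role == "channel_ims"]
  mat <- geom$sites$site_id[geom$sites$role == "channel_matrix"]
  empty <- fomotor:::.empty_events()
  expect_equal(as.numeric(net_flux(empty, geom)), 0)
  ev <- data.frame(phase_index = c(2L, 5L), donor = c(ims, 1L),
                   acceptor = c(1L, mat), r = 3, theta = 180, weight = 1,
                   delta_e = -1, accepted = TRUE, leak_flag = FALSE)
  nf <- net_flux(ev, geom)
  expect_equal(as.numeric(nf), 1)
  expect_equal(attr(nf, "ims_uptake"), 1)
  # a rejected event counts for nothing
  ev$accepted <- c(TRUE, FALSE)
  expect_equal(as.numeric(net_flux(ev, geom)), 0)
})

test_that("leak detection counts straddles and short-rotation itineraries", {
  traj <- make_scripted_traj()
  ims <- geom$sites$site_id[geom$sites$role == "channel_ims"]
  mat <- geom$sites$site_id[geom$sites$role == "channel_matrix"]
  # one accepted straddling transfer
  ev1 <- data.frame(phase_index = 3L, donor = ims, acceptor = 1L, r = 13,
                    theta = 160, weight = 0.02, delta_e = -1,
                    accepted = TRUE, leak_flag = TRUE)
  lk <- detect_leaks(ev1, traj)
  expect_equal(lk$straddle, 1L)
  # an itinerary: uptake from the IMS channel then release to the matrix
  # channel with almost no ring rotation in between (phases 3 and 5 share
  # phi_cumulative = -30 in the fixture)
  ev2 <- data.frame(phase_index = c(3L, 5L), donor = c(ims, 1L),
                    acceptor = c(1L, mat), r = 3, theta = 180, weight = 1,
                    delta_e = -1, accepted = TRUE, leak_flag = FALSE)
  lk2 <- detect_leaks(ev2, traj, window = 10)
  expect_equal(lk2$straddle, 0L)
  expect_equal(lk2$itinerary, 1L)
  expect_equal(lk2$total, 1L)
  # the same itinerary with a full step of rotation in between is no leak
  traj2 <- traj
  traj2$phases$phi_cumulative[5] <- traj2$phases$phi_cumulative[3] + 36
  expect_equal(detect_leaks(ev2, traj2, window = 10)$total, 0L)
})

test_that("the four-phase decomposition recovers scripted boundaries", {
  traj <- make_scripted_traj()
  segs <- four_phase_decomposition(traj, "a")
  expect_equal(segs$phase_kind,
               c("resting", "release", "deprotonated_rotation", "uptake",
                 "resting"))
  expect_equal(segs$start, c(1L, 3L, 5L, 6L, 9L))
  expect_equal(segs$end, c(2L, 4L, 5L, 8L, 12L))
  # the segments partition the trajectory
  expect_equal(sum(segs$length), nrow(traj$phases))
  # a subunit that never cycles yields an empty table with a message
  expect_message(none <- four_phase_decomposition(traj, "c"), "never completes")
  expect_equal(nrow(none), 0L)
})

test_that("free-energy curves from samples behave like -ln(histogram)", {
  set.seed(17)
  # uniform angles: flat curve up to sampling noise
  flat <- fes_angle(runif(1e5, 0, 360), bin_width = 2)
  expect_lt(max(flat$f, na.rm = TRUE) - min(flat$f, na.rm = TRUE), 0.5)
  # wrapped-normal angles: curvature of the recovered well matches 1/(2 s^2)
  s <- 10
  x <- rnorm(30000, 180, s)
  f <- fes_angle(x, bin_width = 2)
  sel <- !is.na(f$f) & abs(f$phi - 180) < 12
  fit <- lm(f$f[sel] ~ I((f$phi[sel] - 180)^2))
  expect_equal(unname(coef(fit)[2]), 1 / (2 * s^2), tolerance = 0.10)
  expect_error(fes_angle(x, bin_width = 7), "divide")
})

test_that("sampled angle free energy matches the direct potential scan", {
  en <- energy_params()
  h <- c(1L, rep(0L, 11))   # one deprotonated carrier
  prof <- potential_profile(protonation_state(geom, h), geom, en)
  phi_min_direct <- prof$phi[which.min(prof$f)]
  dyn <- dyn_params(steps_per_segment = 200)
  x <- sample_angles_fixed_h(geom, h, en, dyn, n_segments = 15000, seed = 5)
  bw <- 6
  f <- fes_angle(x, bin_width = bw)
  phi_min_sampled <- f$phi[which.min(f$f)]
  expect_lt(abs(fomotor:::wrap180(phi_min_sampled - phi_min_direct)), bw)
  # pointwise agreement with direct Boltzmann integration of the potential
  # (per-bin weights from a fine-grid quadrature of exp(-V))
  grid <- seq(0, 360 - 0.25, by = 0.25)
  vg <- vapply(grid, function(p) {
    fomotor:::.v_state(protonation_state(geom, h), geom, ring_state(p), en)
  }, numeric(1))
  w <- exp(-(vg - min(vg)))
  bin_of <- floor(grid / bw) + 1L
  p_bin <- as.numeric(rowsum(w, bin_of)) / sum(w)
  f_ref <- -log(p_bin / bw)
  f_ref <- f_ref - min(f_ref)
  sel <- !is.na(f$f) & f$count >= 100
  offset <- mean(f$f[sel] - f_ref[sel])
  expect_lt(max(abs(f$f[sel] - f_ref[sel] - offset)), 0.3)
})
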