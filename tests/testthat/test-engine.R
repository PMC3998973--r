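# Engine-level properties: exact conservation, determinism, causality,
# thermostat behaviour, frame schedules and the relaxation protocol.

test_that("microcanonical segments conserve energy and momentum exactly", {
  sys <- ala_system(10)
  warm <- run_segment(build_extended(sys$topo), sys$ff, temperature = 0.6,
                      duration = 50, save_every = 10, seed = 3, hex = 1)
  tr <- run_segment(warm$final, sys$ff, temperature = 0.6, duration = 150,
                    save_every = 1, seed = 4, hex = 0,
                    init_velocities = FALSE)
  expect_gte(tr$n_events, 1e4)
  expect_equal(tr$n_ghosts, 0)
  etot <- tr$obs$E + tr$obs$K
  expect_lt(max(abs(etot - etot[1])), 1e-8)
  p0 <- colSums(warm$final$vel)
  p1 <- colSums(tr$final$vel)
  expect_lt(max(abs(p1 - p0)), 1e-10)
})

test_that("engine bookkeeping agrees with the from-scratch energy", {
  sys <- ala_system(8)
  tr <- run_segment(build_extended(sys$topo), sys$ff, temperature = 0.55,
                    duration = 120, save_every = 30, seed = 11, hex = 0.2)
  expect_equal(tr$final$energy, potential_energy(sys$ff, tr$final),
               tolerance = 1e-10)
})

test_that("no pair is ever left inside a hard core or outside a bond window", {
  sys <- ala_system(8)
  tr <- run_segment(build_extended(sys$topo), sys$ff, temperature = 0.65,
                    duration = 100, save_every = 100, seed = 13, hex = 0.3)
  conf <- tr$final
  d <- as.matrix(dist(conf$xyz))
  viol <- sys$ff$sigma > 0 & d < sys$ff$sigma * (1 - 1e-6)
  expect_false(any(viol[upper.tri(viol)]))
  b <- sys$topo$bonds
  db <- d[cbind(b$i, b$j)]
  expect_true(all(db >= b$dmin * (1 - 1e-6) & db <= b$dmax * (1 + 1e-6)))
})

test_that("same seed gives bit-identical trajectories", {
  sys <- ala_system(6)
  conf <- build_extended(sys$topo)
  a <- run_segment(conf, sys$ff, 0.6, 60, 10, seed = 9)
  b <- run_segment(conf, sys$ff, 0.6, 60, 10, seed = 9)
  expect_identical(a$frames, b$frames)
  expect_identical(a$obs, b$obs)
  c <- run_segment(conf, sys$ff, 0.6, 60, 10, seed = 10)
  expect_false(identical(a$frames, c$frames))
})

test_that("frame schedule yields floor(duration/save_every) frames", {
  sys <- ala_system(4)
  conf <- build_extended(sys$topo)
  tr <- run_segment(conf, sys$ff, 0.6, duration = 1000, save_every = 200,
                    seed = 2)
  expect_equal(nrow(tr$obs), 5L)
  expect_equal(tr$obs$time, c(200, 400, 600, 800, 1000))
  tr2 <- run_segment(conf, sys$ff, 0.6, duration = 130, save_every = 40,
                     seed = 2)
  expect_equal(nrow(tr2$obs), schedule_frames(130, 40))
  expect_equal(nrow(tr2$obs), 3L)
})

test_that("schedule enumeration matches the production protocol arithmetic", {
  expect_identical(schedule_frames(1e6, 200), 5000L)
  expect_identical(schedule_frames(1000, 200), 5L)
  # segmented runs cover the same global grid
  expect_identical(schedule_frames(1000, 200, t_start = 0) +
                     schedule_frames(1000, 200, t_start = 1000),
                   schedule_frames(2000, 200))
})

test_that("thermostatted runs reach equipartition at the target temperature", {
  sys <- ala_system(10)
  tr <- run_segment(build_extended(sys$topo), sys$ff, temperature = 0.6,
                    duration = 400, save_every = 1, seed = 5, hex = 0.5)
  sel <- tr$obs$time > 100
  ke_dof <- tr$obs$K[sel] / (3 * sys$topo$n_beads)
  se <- sd(ke_dof) / sqrt(sum(sel) / 5)  # conservative correlation factor
  expect_lt(abs(mean(ke_dof) - 0.3), 3 * se)
})

test_that("HEX = 0 schedules no ghosts and doubling HEX doubles the rate", {
  toy <- gen_two_state_toy()
  s0 <- simulate_two_state(toy, 0.6, duration = 2000, seed = 1, hex = 0)
  expect_equal(s0$n_ghosts, 0)
  s1 <- simulate_two_state(toy, 0.6, duration = 4000, seed = 2, hex = 1)
  s2 <- simulate_two_state(toy, 0.6, duration = 4000, seed = 3, hex = 2)
  # ghost totals are Poisson(hex * n_beads * duration), n_beads = 2
  for (pair in list(list(s1, 1), list(s2, 2))) {
    lam <- pair[[2]] * 2 * 4000
    expect_lt(abs(pair[[1]]$n_ghosts - lam), 3 * sqrt(lam))
  }
})

test_that("minimize applies the two-stage protocol and honours restraints", {
  proto <- minimize_protocol()
  expect_equal(length(proto$stages), 2L)
  expect_equal(proto$stages[[1]][c("duration", "hex", "temperature")],
               list(duration = 1000, hex = 10, temperature = 0.7))
  expect_equal(proto$stages[[2]][c("duration", "hex", "temperature")],
               list(duration = 1000, hex = 0.1, temperature = 0.5))
  expect_equal(proto$restraint_halfwidth, 0.5)

  sys <- ala_system(8)
  conf <- build_extended(sys$topo)
  # shortened stages keep the unit test fast; restraint contract is unchanged
  proto$stages[[1]]$duration <- 100
  proto$stages[[2]]$duration <- 100
  out <- minimize(conf, sys$ff, protocol = proto, seed = 21)
  keep <- sys$topo$beads$kind %in% c("CA", "CB")
  disp <- sqrt(rowSums((out$xyz[keep, ] - conf$xyz[keep, ])^2))
  expect_lte(max(disp), 0.5 * (1 + 1e-6))
  expect_true(is.finite(potential_energy(sys$ff, out)))
  d <- sqrt(rowSums((out$xyz[sys$topo$bonds$i, ] -
                     out$xyz[sys$topo$bonds$j, ])^2))
  expect_true(all(d >= sys$topo$bonds$dmin * (1 - 1e-6)))
  expect_true(all(d <= sys$topo$bonds$dmax * (1 + 1e-6)))
})
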