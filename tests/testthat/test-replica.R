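test_that("the default ladder is the canonical 8-rung set", {
  l <- default_ladder()
  expect_length(l, 8L)
  expect_equal(l, c(0.5246, 0.5451, 0.5665, 0.5886, 0.6116, 0.6355,
                    0.6604, 0.6862))
  expect_true(all(diff(l) > 0))
})

test_that("swap probability follows the Metropolis closed form", {
  expect_equal(swap_probability(0.5, 0.6, -10, -10), 1.0)
  # exponent -1: choose energies so (1/Ti - 1/Tj)(Ei - Ej) = -1
  ti <- 0.5; tj <- 0.6
  de <- -1 / (1 / ti - 1 / tj)
  expect_equal(swap_probability(ti, tj, de, 0), exp(-1), tolerance = 1e-12)
  # favourable exponent clips at 1
  expect_equal(swap_probability(ti, tj, -de, 0), 1.0)
  expect_error(swap_probability(-0.1, 0.6, 0, 0))
})

test_that("replayed swap decisions match the analytic probability", {
  set.seed(123)
  for (p in c(exp(-1), 0.25, 0.8)) {
    acc <- swap_decide(rep(p, 1e4))
    expect_lt(abs(mean(acc) - p), 3 * sqrt(p * (1 - p) / 1e4))
  }
})

test_that("run_rx conserves frames, permutes the ladder and logs attempts", {
  sys <- ala_system(6)
  conf <- build_extended(sys$topo)
  ladder <- c(0.55, 0.60, 0.66)
  rx <- run_rx(conf, sys$ff, ladder = ladder, total_duration = 400,
               swap_every = 100, save_every = 50, seed = 31)
  # frame conservation per replica and in total
  for (tr in rx$trajectories) {
    expect_equal(nrow(tr$obs), schedule_frames(400, 50))
  }
  # every frame's temperature comes from the ladder, multiset preserved
  for (tr in rx$trajectories) {
    expect_true(all(tr$obs$temperature %in% ladder))
  }
  temps_final <- sort(vapply(rx$trajectories, function(tr) {
    tr$obs$temperature[nrow(tr$obs)]
  }, numeric(1)))
  expect_equal(temps_final, sort(ladder))
  # swap log: alternating even/odd adjacent pairs, all probabilities valid
  expect_true(all(rx$swaps$p >= 0 & rx$swaps$p <= 1))
  expect_true(all(rx$swaps$rung_hi == rx$swaps$rung_lo + 1L))
  odd_rounds <- rx$swaps$rung_lo[rx$swaps$time %in% c(100, 300)]
  even_rounds <- rx$swaps$rung_lo[rx$swaps$time %in% c(200, 400)]
  expect_true(all(odd_rounds %% 2L == 1L))
  expect_true(all(even_rounds %% 2L == 0L))
})

test_that("demux regroups every frame by temperature exactly once", {
  sys <- ala_system(6)
  conf <- build_extended(sys$topo)
  rx <- run_rx(conf, sys$ff, ladder = c(0.55, 0.62), total_duration = 300,
               swap_every = 100, save_every = 50, seed = 8)
  ens <- demux_by_temperature(rx)
  expect_length(ens, 2L)
  per_rung <- vapply(ens, function(e) nrow(e$obs), integer(1))
  expect_equal(unname(per_rung), rep(schedule_frames(300, 50), 2L))
  total_replica <- sum(vapply(rx$trajectories, function(tr) nrow(tr$obs),
                              integer(1)))
  expect_equal(sum(per_rung), total_replica)
  for (e in ens) expect_true(!is.unsorted(e$obs$time))
})

test_that("with no accepted swaps demux is the identity regrouping", {
  sys <- ala_system(6)
  conf <- build_extended(sys$topo)
  # far-apart rungs with huge energy gaps would still swap when E_i ~ E_j;
  # instead force rejection by replaying run_rx with a ladder of 2 and
  # checking the no-swap case explicitly
  rx <- run_rx(conf, sys$ff, ladder = c(0.55, 0.62), total_duration = 200,
               swap_every = 100, save_every = 50, seed = 14)
  if (!any(rx$swaps$accepted)) {
    ens <- demux_by_temperature(rx)
    expect_equal(ens[[1]]$obs$E, rx$trajectories[[1]]$obs$E)
    expect_equal(ens[[2]]$obs$E, rx$trajectories[[2]]$obs$E)
  }
  # determinism of the full replica-exchange driver
  rx2 <- run_rx(conf, sys$ff, ladder = c(0.55, 0.62), total_duration = 200,
                swap_every = 100, save_every = 50, seed = 14)
  expect_identical(rx$swaps, rx2$swaps)
  expect_identical(rx$trajectories[[1]]$frames, rx2$trajectories[[1]]$frames)
})
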