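test_that("torsions round-trip through the chain builder", {
  topo <- ala_topo(8)
  tor <- compute_torsions(build_ideal_helix(topo))
  expect_true(is.na(tor$phi[1]))
  expect_true(is.na(tor$psi[8]))
  expect_equal(tor$phi[2:8], rep(-57, 7), tolerance = 1e-6)
  expect_equal(tor$psi[1:7], rep(-47, 7), tolerance = 1e-6)
  # construct numbering honours the offset
  topo2 <- build_topology(residue_seq(strrep("A", 5), offset = 101))
  expect_equal(compute_torsions(build_extended(topo2))$residue, 101:105)
})

test_that("dihedral sign convention agrees with an independent implementation", {
  topo <- ala_topo(6)
  conf <- build_ideal_helix(topo)
  ours <- compute_torsions(conf)
  # bio3d as external oracle on the same coordinates
  bm <- rexdmd:::bead_index_matrix(topo)
  for (i in 3:5) {
    ref_phi <- bio3d::torsion.xyz(as.vector(t(conf$xyz[c(bm[i - 1, "C"],
                                                         bm[i, "N"],
                                                         bm[i, "CA"],
                                                         bm[i, "C"]), ])))
    expect_equal(ours$phi[i], as.numeric(ref_phi), tolerance = 1e-6)
  }
})

test_that("helical assignment uses open intervals and rejects NA", {
  expect_true(assign_helical(-57, -47))
  expect_false(assign_helical(180, 180))
  expect_false(assign_helical(NA, -47))
  w <- helical_window()
  expect_false(assign_helical(w$phi[1], -47))   # boundary excluded
  expect_false(assign_helical(-57, w$psi[2]))
  expect_equal(assign_helical(c(-57, 180), c(-47, 180)), c(TRUE, FALSE))
})

test_that("propensity is the exact per-residue count ratio", {
  # deterministic ensemble: residue 2 helical in exactly half the frames
  phi <- matrix(-170, 4, 3)
  psi <- matrix(150, 4, 3)
  phi[c(1, 3), 2] <- -57
  psi[c(1, 3), 2] <- -47
  ens <- temperature_ensemble(NULL, 0.55, phi = phi, psi = psi,
                              aa = rep("A", 3), offset = 10L)
  pr <- propensity_profile(ens)
  expect_equal(pr$propensity, c(0, 0.5, 0))
  expect_equal(pr$residue, 10:12)
  # brute-force per-frame recount on a random ensemble
  gen <- gen_torsion_ensemble(p = c(0.2, 0.8, 0.5), n_frames = 400,
                              persistence = 0.3, seed = 5)
  pr2 <- propensity_profile(gen)
  manual <- colMeans(assign_helical(gen$phi, gen$psi))
  expect_equal(pr2$propensity, unname(manual))
})

test_that("propensity is invariant to frame order and rigid motions", {
  sys <- ala_system(6)
  tr <- run_segment(build_extended(sys$topo), sys$ff, 0.6, 100, 10, seed = 2)
  ens <- temperature_ensemble(sys$topo, 0.6, xyz = tr$frames, obs = tr$obs)
  p0 <- propensity_profile(ens)$propensity
  # reorder frames
  ord <- rev(seq_len(dim(tr$frames)[3]))
  ens2 <- temperature_ensemble(sys$topo, 0.6,
                               xyz = tr$frames[, , ord, drop = FALSE],
                               obs = tr$obs[ord, ])
  expect_equal(propensity_profile(ens2)$propensity, p0)
  # rigid rotation + translation of every frame
  R <- random_rotation(77)
  arr <- tr$frames
  for (f in seq_len(dim(arr)[3])) {
    arr[, , f] <- arr[, , f] %*% R + matrix(c(5, -3, 2), dim(arr)[1], 3,
                                            byrow = TRUE)
  }
  ens3 <- temperature_ensemble(sys$topo, 0.6, xyz = arr, obs = tr$obs)
  expect_equal(propensity_profile(ens3)$propensity, p0, tolerance = 1e-9)
})

test_that("helix run maps keep maximal runs of at least min_run", {
  phi <- matrix(-170, 2, 20)
  psi <- matrix(150, 2, 20)
  phi[1, 10:15] <- -57; psi[1, 10:15] <- -47   # one 6-run
  phi[2, 3:5] <- -57; psi[2, 3:5] <- -47       # one 3-run
  ens <- temperature_ensemble(NULL, 0.55, phi = phi, psi = psi,
                              aa = rep("A", 20), offset = 1L)
  hm <- helix_run_map(ens, min_run = 4)
  expect_equal(nrow(hm), 1L)
  expect_equal(c(hm$frame, hm$start, hm$end), c(1L, 10L, 15L))
  hm2 <- helix_run_map(ens, min_run = 3)
  expect_equal(nrow(hm2), 2L)
})

test_that("with min_run = 1 the run map averages back to the propensity", {
  gen <- gen_torsion_ensemble(p = rep(0.4, 8), n_frames = 300,
                              persistence = 0.5, seed = 9)
  hm <- helix_run_map(gen, min_run = 1)
  cover <- numeric(8)
  for (k in seq_len(nrow(hm))) {
    cover[hm$start[k]:hm$end[k]] <- cover[hm$start[k]:hm$end[k]] + 1
  }
  expect_equal(cover / 300, propensity_profile(gen)$propensity)
})

test_that("radius of gyration has its closed forms and invariances", {
  # two CA beads distance d apart -> d/2
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(3, 0, 0))), 1.5)
  # 7 collinear beads spacing 1: sqrt((49 - 1)/12) = 2
  expect_equal(radius_of_gyration(gen_geometry("collinear", length = 7,
                                               spacing = 1)), 2,
               tolerance = 1e-9)
  # CA-only contract: moving CB/N/C beads leaves Rg unchanged
  sys <- ala_system(6)
  conf <- build_ideal_helix(sys$topo)
  rg0 <- radius_of_gyration(conf)
  conf2 <- conf
  notca <- sys$topo$beads$kind != "CA"
  conf2$xyz[notca, ] <- conf2$xyz[notca, ] + 10
  expect_equal(radius_of_gyration(conf2), rg0)
  # rotation/translation invariance
  R <- random_rotation(3)
  conf3 <- conf
  conf3$xyz <- conf$xyz %*% R + matrix(c(1, 2, 3), nrow(conf$xyz), 3,
                                       byrow = TRUE)
  expect_equal(radius_of_gyration(conf3), rg0, tolerance = 1e-9)
})

test_that("DoS surfaces obey the Sippl identity exactly", {
  set.seed(41)
  n <- 500
  obs <- data.frame(frame = 1:n, time = 1:n,
                    Rg = runif(n, 5, 15), E = runif(n, -30, 0))
  ens <- temperature_ensemble(NULL, 0.5886, phi = matrix(-57, n, 3),
                              psi = matrix(-47, n, 3), aa = rep("A", 3),
                              offset = 1L, obs = obs)
  ds <- dos_surface(ens, n_bins_rg = 8, n_bins_e = 8)
  expect_equal(sum(ds$P), 1)
  occ <- which(ds$counts > 0, arr.ind = TRUE)
  expect_true(all(is.na(ds$dos[ds$counts == 0])))
  # DoS differences depend only on count ratios and T
  a <- occ[1, ]; b <- occ[nrow(occ), ]
  expect_equal(ds$dos[a[1], a[2]] - ds$dos[b[1], b[2]],
               -0.5886 * log(ds$counts[a[1], a[2]] / ds$counts[b[1], b[2]]),
               tolerance = 1e-12)
  # uniform occupancy gives a flat surface
  obs2 <- obs
  obs2$Rg <- rep(c(6, 12), length.out = n)
  obs2$E <- rep(c(-20, -10), length.out = n)
  ens2 <- temperature_ensemble(NULL, 0.6, phi = matrix(-57, n, 3),
                               psi = matrix(-47, n, 3), aa = rep("A", 3),
                               offset = 1L, obs = obs2)
  ds2 <- dos_surface(ens2, n_bins_rg = 2, n_bins_e = 2)
  vals <- ds2$dos[!is.na(ds2$dos)]
  expect_lt(diff(range(vals)), 1e-12)
  # degenerate axis collapses to one bin with a warning
  obs3 <- obs
  obs3$Rg <- rep(7, n)
  ens3 <- temperature_ensemble(NULL, 0.6, phi = matrix(-57, n, 3),
                               psi = matrix(-47, n, 3), aa = rep("A", 3),
                               offset = 1L, obs = obs3)
  expect_warning(ds3 <- dos_surface(ens3), "degenerate")
  expect_equal(nrow(ds3$P), 1L)
})

test_that("ordered chains carve a deeper, more populated DoS basin than disordered ones", {
  # strongly stabilised chain vs weak-well polyalanine at the same length
  sysS <- ala_system(12, overrides = list(hb_eps = 6, hb_torsion_well = 1.2,
                                          hb_chiral_torsion_well = 0.8))
  sysW <- ala_system(12, overrides = list(hb_eps = 0.5, hb_torsion_well = 0.05,
                                          hb_chiral_torsion_well = 0.05,
                                          hb_contact_well = 0.05))
  mk_ens <- function(sys, seed) {
    tr <- run_segment(build_ideal_helix(sys$topo), sys$ff, 0.5665,
                      duration = 1500, save_every = 3, seed = seed, hex = 0.1)
    sel <- tr$obs$time > 300
    temperature_ensemble(sys$topo, 0.5665,
                         xyz = tr$frames[, , sel, drop = FALSE],
                         obs = tr$obs[sel, ])
  }
  dsS <- dos_surface(mk_ens(sysS, 3), n_bins_rg = 12, n_bins_e = 12)
  dsW <- dos_surface(mk_ens(sysW, 3), n_bins_rg = 12, n_bins_e = 12)
  pmin_S <- dsS$P[which.min(dsS$dos)]   # occupancy of the deepest basin
  pmin_W <- dsW$P[which.min(dsW$dos)]
  expect_gt(pmin_S, pmin_W)
})

test_that("ramachandran occupancies resolve the named regions", {
  # ensemble entirely at (-90, 0): all points in AT1
  n <- 50
  ens <- temperature_ensemble(NULL, 0.6, phi = matrix(-90, n, 4),
                              psi = matrix(0, n, 4), aa = rep("A", 4),
                              offset = 1L)
  ro <- ramachandran_occupancy(ens)
  expect_equal(unname(ro$fractions["AT1"]), 1.0)
  expect_equal(unname(ro$fractions["AG"]), 0.0)
  expect_true(is.na(ro$gly["AT1"]))  # no glycine in the sequence
  # pairwise-disjoint regions have fractions summing to at most 1
  # (extended, AT1 and AG share no torsion-space area; the helical window
  # overlaps the transition corridors by construction)
  gen <- gen_torsion_ensemble(p = rep(0.5, 6), n_frames = 200,
                              persistence = 0, seed = 3)
  ro2 <- ramachandran_occupancy(gen)
  disjoint <- ro2$fractions[c("extended", "AT1", "AG")]
  expect_lte(sum(disjoint), 1)
  expect_true(all(ro2$fractions >= 0 & ro2$fractions <= 1, na.rm = TRUE))
})

test_that("uniform glycine torsions populate AG evenly", {
  set.seed(8)
  n <- 4000
  phi <- matrix(runif(n * 2, -180, 180), n, 2)
  psi <- matrix(runif(n * 2, -180, 180), n, 2)
  ens <- temperature_ensemble(NULL, 0.6, phi = phi, psi = psi,
                              aa = c("G", "G"), offset = 1L)
  ro <- ramachandran_occupancy(ens)
  expect_equal(unname(ro$gly["AG"]), 0.5, tolerance = 0.05)
  # evenness over a coarse grid of the positive-phi half-plane
  sel <- phi > 0
  counts <- table(cut(phi[sel], seq(0, 180, 60)),
                  cut(psi[sel], seq(-180, 180, 90)))
  expect_lt(max(counts) / min(counts), 1.5)
})
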