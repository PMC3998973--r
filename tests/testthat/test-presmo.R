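mk_profile <- function(values, offset = 1L, temperature = 0.5886) {
  structure(data.frame(residue = seq_along(values) + offset - 1L,
                       propensity = values),
            class = c("propensity_profile", "data.frame"),
            n_frames = 1000L, temperature = temperature, offset = offset)
}

test_that("call_regions finds plateaus, merges small gaps, drops short runs", {
  v <- rep(0, 30)
  v[10:20] <- 0.6
  calls <- call_regions(mk_profile(v), threshold = 0.2)
  expect_equal(nrow(calls), 1L)
  expect_equal(c(calls$start, calls$end), c(10L, 20L))
  expect_equal(calls$peak, 0.6)

  # all sub-threshold: nothing called
  expect_equal(nrow(call_regions(mk_profile(rep(0.1, 20)))), 0L)

  # two plateaus split by one sub-threshold residue
  v2 <- rep(0, 30)
  v2[5:9] <- 0.5
  v2[11:15] <- 0.5
  c0 <- call_regions(mk_profile(v2), threshold = 0.2, max_gap = 0)
  expect_equal(nrow(c0), 2L)
  c1 <- call_regions(mk_profile(v2), threshold = 0.2, max_gap = 1)
  expect_equal(nrow(c1), 1L)
  expect_equal(c(c1$start, c1$end), c(5L, 15L))

  # min_len filter applies after merging
  v3 <- rep(0, 20)
  v3[4:6] <- 0.9
  expect_equal(nrow(call_regions(mk_profile(v3), min_len = 4)), 0L)
  expect_equal(nrow(call_regions(mk_profile(v3), min_len = 3)), 1L)

  # construct numbering honoured
  cko <- call_regions(mk_profile(v, offset = 101L), threshold = 0.2)
  expect_equal(c(cko$start, cko$end), c(110L, 120L))
})

test_that("call_regions is monotone in the threshold", {
  # raising the threshold never enlarges a region: the called residue set
  # shrinks and every high-threshold region is contained in a low-threshold
  # one (a region may split, never grow)
  covered <- function(calls, L) {
    out <- rep(FALSE, L)
    for (k in seq_len(nrow(calls))) out[calls$start[k]:calls$end[k]] <- TRUE
    out
  }
  set.seed(12)
  for (rep in 1:20) {
    v <- pmin(1, pmax(0, cumsum(rnorm(40, sd = 0.15)) %% 1))
    lo <- call_regions(mk_profile(v), threshold = 0.2, min_len = 1)
    hi <- call_regions(mk_profile(v), threshold = 0.35, min_len = 1)
    expect_true(all(covered(hi, 40) <= covered(lo, 40)))
    for (k in seq_len(nrow(hi))) {
      expect_true(any(lo$start <= hi$start[k] & lo$end >= hi$end[k]))
    }
  }
})

test_that("round trip: plateau profiles are recovered exactly", {
  v <- rep(0.05, 40)
  v[8:14] <- 0.35
  v[25:33] <- 0.8
  calls <- call_regions(mk_profile(v), threshold = 0.2, min_len = 4)
  expect_equal(calls$start, c(8L, 25L))
  expect_equal(calls$end, c(14L, 33L))
})

test_that("matching uses the boundary rule with the +/-2 tolerance", {
  ref <- data.frame(name = "KID", start = 119L, end = 129L)
  pred <- data.frame(start = 121L, end = 130L)
  rep1 <- match_regions(pred, ref, boundary_tol = 2)
  expect_true(rep1$matched)
  expect_equal(rep1$rule, "boundary")

  # identical intervals match trivially
  rep2 <- match_regions(data.frame(start = 10L, end = 20L),
                        data.frame(start = 10L, end = 20L))
  expect_true(rep2$matched)

  # disjoint intervals do not
  rep3 <- match_regions(data.frame(start = 40L, end = 50L),
                        data.frame(start = 10L, end = 20L))
  expect_false(rep3$matched)
  expect_equal(attr(rep3, "n_extra"), 1L)
})

test_that("the overlap rule fires on half the shorter interval", {
  ref <- data.frame(start = 10L, end = 29L)      # length 20
  pred <- data.frame(start = 24L, end = 33L)     # length 10, overlap 6
  expect_false(match_regions(pred, ref, min_overlap_frac = 0.7)$matched)
  rep2 <- match_regions(pred, ref, min_overlap_frac = 0.5)
  expect_true(rep2$matched)
  expect_equal(rep2$rule, "overlap")
})

test_that("matching is invariant under a common shift", {
  ref <- data.frame(start = 119L, end = 129L)
  pred <- data.frame(start = 121L, end = 130L)
  for (shift in c(-50L, 0L, 200L)) {
    m <- match_regions(transform(pred, start = start + shift,
                                 end = end + shift),
                       transform(ref, start = start + shift,
                                 end = end + shift))
    expect_true(m$matched)
  }
})

test_that("benchmark_summary aggregates detection counts", {
  mk_report <- function(n_ref, n_det) {
    structure(data.frame(start = seq_len(n_ref), end = seq_len(n_ref) + 5L,
                         matched = c(rep(TRUE, n_det),
                                     rep(FALSE, n_ref - n_det))),
              class = c("match_report", "data.frame"),
              n_reference = n_ref, n_detected = n_det,
              fraction = n_det / n_ref, n_extra = 0L)
  }
  # 65 reference regions of which 45 detected, split over proteins
  reports <- list(mk_report(30L, 20L), mk_report(20L, 15L), mk_report(15L, 10L))
  s <- benchmark_summary(reports)
  expect_equal(s$n_reference, 65)
  expect_equal(s$n_detected, 45)
  expect_equal(s$fraction, 45 / 65, tolerance = 1e-12)

  expect_error(benchmark_summary(list(mk_report(0L, 0L))), "no reference")
  expect_equal(benchmark_summary(list(mk_report(4L, 4L)))$fraction, 1.0)
})

test_that("cross-temperature confirmation flags regions present at adjacent rungs", {
  v <- rep(0, 30)
  v[10:18] <- 0.5
  profs <- list(mk_profile(v), mk_profile(v), mk_profile(rep(0, 30)))
  calls <- call_regions_confirmed(profs, rung = 1)
  expect_true(all(calls$confirmed))
  calls3 <- call_regions_confirmed(profs, rung = 3)
  expect_equal(nrow(calls3), 0L)
})
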