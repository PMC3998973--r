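# shared builders for small test systems (all deterministic)

ala_topo <- function(n = 10L, params = ff_params()) {
  build_topology(residue_seq(strrep("A", n)), params)
}

ala_system <- function(n = 10L, overrides = list()) {
  params <- ff_params(overrides = overrides)
  topo <- build_topology(residue_seq(strrep("A", n)), params)
  list(topo = topo, ff = compile_forcefield(topo, params), params = params)
}

# independent brute-force potential energy oracle: plain double loop over all
# pairs and rule definitions, sharing no code with potential_energy()
brute_energy <- function(ff, conf) {
  xyz <- conf$xyz
  n <- nrow(xyz)
  dij <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  for (k in seq_len(nrow(ff$topo$bonds))) {
    b <- ff$topo$bonds[k, ]
    d <- dij(b$i, b$j)
    if (d < b$dmin - 1e-9 || d > b$dmax + 1e-9) return(Inf)
  }
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ff$cls[i, j] == 0L) next
      d <- dij(i, j)
      if (ff$sigma[i, j] > 0 && d < ff$sigma[i, j]) return(Inf)
      if (ff$cls[i, j] == 1L && ff$well_r[i, j] > 0 &&
          d >= ff$sigma[i, j] && d < ff$well_r[i, j]) {
        e <- e - ff$well_depth[i, j]
      }
    }
  }
  if (!is.null(ff$hb_pairs)) {
    for (k in seq_len(nrow(ff$hb_pairs))) {
      p <- ff$hb_pairs[k, ]
      d <- dij(p$i, p$j)
      if (d >= p$lo && d < p$hi) e <- e - p$base
    }
  }
  if (!is.null(ff$hb)) {
    for (r in seq_len(nrow(ff$hb))) {
      m <- ff$hb_members[ff$hb_members$rule == r, ]
      act <- TRUE
      for (k in seq_len(nrow(m))) {
        d <- dij(m$i[k], m$j[k])
        if (d < m$lo[k] || d >= m$hi[k]) { act <- FALSE; break }
      }
      if (act) e <- e - ff$hb$depth[r]
    }
  }
  e
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3)))
}
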