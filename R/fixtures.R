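# Synthetic test inputs with known answers: geometric conformations with
# closed-form observables, torsion ensembles with prescribed per-residue
# helix statistics and along-chain run continuity, and a two-bead square-well
# system with an analytic Boltzmann occupancy ratio. All generators are pure
# functions of (parameters, seed).

#' Generate a geometric fixture
#'
#' \itemize{
#'   \item \code{ideal_helix}: polyalanine chain with internal
#'     (phi, psi) = (-57, -47); returns a \code{dmd_conformation}.
#'   \item \code{extended}: all torsions 180 degrees; returns a
#'     \code{dmd_conformation}.
#'   \item \code{collinear}: \code{length} CA beads on a line with given
#'     \code{spacing}; Rg has the closed form
#'     \code{spacing * sqrt((N^2 - 1) / 12)}. Returns a coordinate matrix.
#'   \item \code{ring}: \code{length} CA beads equally spaced on a circle of
#'     given \code{radius}; Rg = radius. Returns a coordinate matrix.
#' }
#'
#' @param kind fixture kind.
#' @param length number of residues (chain kinds) or beads (geometry kinds).
#' @param spacing collinear spacing (Angstrom).
#' @param radius ring radius (Angstrom).
#' @param sequence residue string for the chain kinds (default polyalanine).
#' @return \code{dmd_conformation} or CA coordinate matrix.
#' @export
gen_geometry <- function(kind = c("ideal_helix", "extended", "collinear",
                                  "ring"),
                         length = 10L, spacing = 1.0, radius = 1.0,
                         sequence = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("ideal_helix", "extended")) {
    if (is.null(sequence)) sequence <- strrep("A", length)
    topo <- build_topology(residue_seq(sequence, name = kind))
    return(if (kind == "ideal_helix") build_ideal_helix(topo)
           else build_extended(topo))
  }
  stopifnot(length >= 1)
  if (kind == "collinear") {
    stopifnot(spacing > 0)
    cbind(spacing * (seq_len(length) - 1), 0, 0)
  } else {
    stopifnot(radius > 0)
    th <- 2 * pi * (seq_len(length) - 1) / length
    cbind(radius * cos(th), radius * sin(th), 0)
  }
}

#' Generate a synthetic torsion ensemble with prescribed helix statistics
#'
#' Per frame, residue helical states form a binary chain whose marginal at
#' residue i converges to \code{p[i]} and whose along-chain continuity is set
#' by \code{persistence} (probability that residue i copies the state of
#' residue i-1). Helical residues draw (phi, psi) uniformly inside the
#' helical torsion window; non-helical residues draw from the extended basin
#' (phi in (-180, -60), psi in (60, 180)). All angles are defined, including
#' at the termini.
#'
#' @param p per-residue helical probability vector, values in [0, 1].
#' @param n_frames number of frames.
#' @param persistence along-chain copy probability in [0, 1).
#' @param seed mandatory integer seed.
#' @param window helical torsion window.
#' @param aa residue codes (defaults to polyalanine).
#' @param offset construct numbering of residue 1.
#' @param temperature label attached to the ensemble.
#' @return \code{temperature_ensemble} carrying torsions (no coordinates).
#' @export
gen_torsion_ensemble <- function(p, n_frames, persistence = 0, seed,
                                 window = helical_window(),
                                 aa = rep("A", length(p)), offset = 1L,
                                 temperature = NA_real_) {
  stopifnot(all(p >= 0), all(p <= 1), persistence >= 0, persistence < 1,
            n_frames >= 1, length(aa) == length(p))
  L <- length(p)
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state)) assign(".Random.seed", rng_state,
                                    envir = globalenv())
  })
  set.seed(as.integer(seed))

  # heterogeneous two-state Markov chain along the chain with exact
  # marginals: P(h_i = 1 | h_{i-1}) = p_i +/- c_i with
  # c_i = persistence * (feasible coupling), which preserves the requested
  # marginal for any coupling and reduces to independent draws at
  # persistence 0
  h <- matrix(FALSE, n_frames, L)
  h[, 1L] <- stats::runif(n_frames) < p[1L]
  if (L > 1L) {
    for (i in 2:L) {
      pm <- p[i - 1L]
      cmax <- if (pm <= 0 || pm >= 1) 0 else
        min(1, (1 - p[i]) / (1 - pm), p[i] / pm)
      ci <- persistence * cmax
      p_on <- p[i] + (1 - pm) * ci    # P(1 | previous = 1)
      p_off <- p[i] - pm * ci         # P(1 | previous = 0)
      u <- stats::runif(n_frames)
      h[, i] <- ifelse(h[, i - 1L], u < p_on, u < p_off)
    }
  }
  ru <- function(n, lo, hi) lo + (hi - lo) * stats::runif(n)
  nh <- sum(h)
  phi <- matrix(NA_real_, n_frames, L)
  psi <- matrix(NA_real_, n_frames, L)
  phi[h] <- ru(nh, window$phi[1], window$phi[2])
  psi[h] <- ru(nh, window$psi[1], window$psi[2])
  phi[!h] <- ru(n_frames * L - nh, -180, -60)
  psi[!h] <- ru(n_frames * L - nh, 60, 180)
  temperature_ensemble(NULL, temperature, phi = phi, psi = psi, aa = aa,
                       offset = offset)
}

#' Two-bead square-well toy system with analytic occupancy
#'
#' Two unit-mass beads interacting through a hard core at \code{core}, a
#' square well of depth \code{well_depth} out to \code{well_r}, confined by a
#' hard outer wall at separation \code{box_radius}. The Boltzmann
#' bound/unbound occupancy ratio at temperature T has the closed form
#' \code{(V_well / V_out) * exp(well_depth / T)} with shell volumes in pair
#' separation space.
#'
#' @param well_depth well depth (> 0, energy units).
#' @param core hard-core separation.
#' @param well_r outer well radius (> core).
#' @param box_radius confinement separation (> well_r).
#' @return object of class \code{two_state_toy} with a
#'   \code{bound_ratio(temperature)} function.
#' @export
gen_two_state_toy <- function(well_depth = 1, core = 1, well_r = 2,
                              box_radius = 3) {
  stopifnot(well_depth >= 0, core > 0, well_r > core, box_radius > well_r)
  v_well <- (4 / 3) * pi * (well_r^3 - core^3)
  v_out <- (4 / 3) * pi * (box_radius^3 - well_r^3)
  structure(list(well_depth = well_depth, core = core, well_r = well_r,
                 box_radius = box_radius, v_well = v_well, v_out = v_out,
                 bound_ratio = function(temperature) {
                   (v_well / v_out) * exp(well_depth / temperature)
                 }),
            class = "two_state_toy")
}

#' Simulate the two-state toy and measure the bound fraction
#'
#' Runs the event engine on the two-bead system at fixed temperature and
#' returns per-frame bound indicators (separation < well radius).
#'
#' @param toy \code{two_state_toy}.
#' @param temperature reduced temperature.
#' @param duration run length (time units).
#' @param save_every frame interval.
#' @param seed engine seed.
#' @param hex thermostat coupling (default 1).
#' @return list with \code{bound} (logical per frame), \code{sep} (per-frame
#'   separations) and \code{n_events}.
#' @export
simulate_two_state <- function(toy, temperature, duration = 2e4,
                               save_every = 2, seed = 1L, hex = 1) {
  x0 <- rbind(c(0, 0, 0), c((toy$core + toy$box_radius) / 2, 0, 0))
  v0 <- matrix(0, 2, 3)
  cls <- matrix(0L, 2, 2)
  zero <- matrix(0, 2, 2)
  res <- .dmd_run_cpp(
    x0, v0, c(1, 1), cls, zero, zero, zero,
    sp_i = 0L, sp_j = 1L, sp_tether = -1L, sp_b0 = 0L, sp_nb = 3L,
    b_r = c(toy$core, toy$well_r, toy$box_radius),
    b_type = c(0L, 2L, 1L), b_du = c(0, -toy$well_depth, 0),
    b_rstart = c(0L, 0L, 0L), b_rcount = c(0L, 0L, 0L),
    edge_rules = integer(0), r_depth = numeric(0),
    r_mstart = integer(0), r_mcount = integer(0),
    mem_sp = integer(0), mem_lo = numeric(0), mem_hi = numeric(0),
    anchors = matrix(0, 1, 3),
    bnd_i = integer(0), bnd_j = integer(0),
    bnd_lo = numeric(0), bnd_hi = numeric(0),
    temperature = temperature, hex = hex, t_start = 0,
    duration = duration, save_every = save_every,
    seed = as.numeric(seed), init_velocities = TRUE, skin = 0.8,
    max_events = 2e9)
  nf <- length(res$frame_t)
  sep <- numeric(nf)
  for (f in seq_len(nf)) {
    sep[f] <- sqrt(sum((res$frames[2, , f] - res$frames[1, , f])^2))
  }
  list(bound = sep < toy$well_r, sep = sep, n_events = res$n_events,
       n_ghosts = res$n_ghosts)
}
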