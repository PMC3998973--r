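# Ensemble analysis: phi/psi torsions, helical-state assignment, per-residue
# propensity profiles, per-frame continuous-helix maps, Ramachandran region
# occupancies, radius of gyration, and density-of-states surfaces.

#' Temperature ensemble container
#'
#' Frames collected at one temperature (from whichever replica held it),
#' with per-frame observables and optional cached torsions.
#'
#' @param topo \code{chain_topology} (or NULL for torsion-only ensembles).
#' @param temperature reduced temperature.
#' @param xyz beads x 3 x n_frames coordinate array, or NULL.
#' @param obs data.frame with one row per frame (time, E, Rg where known).
#' @param phi,psi optional n_frames x n_res torsion matrices (degrees).
#' @param aa one-letter residue codes; taken from \code{topo} when present.
#' @param offset construct numbering of residue 1.
#' @return object of class \code{temperature_ensemble}.
#' @export
temperature_ensemble <- function(topo, temperature, xyz = NULL, obs = NULL,
                                 phi = NULL, psi = NULL, aa = NULL,
                                 offset = NULL) {
  if (!is.null(topo)) {
    aa <- topo$seq$aa
    offset <- topo$seq$offset
  }
  stopifnot(!is.null(aa), !is.null(offset))
  if (is.null(obs)) {
    nf <- if (!is.null(xyz)) dim(xyz)[3] else nrow(phi)
    obs <- data.frame(frame = seq_len(nf), time = seq_len(nf))
  }
  structure(list(topo = topo, temperature = temperature, xyz = xyz,
                 obs = obs, phi = phi, psi = psi, aa = aa,
                 offset = as.integer(offset)),
            class = "temperature_ensemble")
}

#' @export
print.temperature_ensemble <- function(x, ...) {
  cat(sprintf("<temperature_ensemble> T = %g, %d frames, %d residues\n",
              x$temperature, nrow(x$obs), length(x$aa)))
  invisible(x)
}

n_frames <- function(ens) nrow(ens$obs)

# cross product of row-wise 3-vectors
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# dihedral over frames: p1..p4 are nf x 3 matrices
dihedral_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross_rows(n1, b2n)
  wrap_angle(-rad2deg(atan2(rowSums(m1 * n2), rowSums(n1 * n2))))
}

# phi/psi matrices (n_frames x n_res) from a coordinate array
torsions_from_xyz <- function(xyz, topo) {
  bm <- bead_index_matrix(topo)
  nf <- dim(xyz)[3]
  L <- topo$n_res
  slice <- function(id) t(matrix(xyz[id, , ], nrow = 3))  # nf x 3
  phi <- matrix(NA_real_, nf, L)
  psi <- matrix(NA_real_, nf, L)
  for (i in seq_len(L)) {
    if (i > 1L) {
      phi[, i] <- dihedral_rows(slice(bm[i - 1L, "C"]), slice(bm[i, "N"]),
                                slice(bm[i, "CA"]), slice(bm[i, "C"]))
    }
    if (i < L) {
      psi[, i] <- dihedral_rows(slice(bm[i, "N"]), slice(bm[i, "CA"]),
                                slice(bm[i, "C"]), slice(bm[i + 1L, "N"]))
    }
  }
  list(phi = phi, psi = psi)
}

# ensure the ensemble carries torsion matrices; returns the ensemble
ensure_torsions <- function(ens) {
  if (!is.null(ens$phi)) return(ens)
  stopifnot(!is.null(ens$xyz), !is.null(ens$topo))
  tt <- torsions_from_xyz(ens$xyz, ens$topo)
  ens$phi <- tt$phi
  ens$psi <- tt$psi
  ens
}

#' Backbone torsion angles of one conformation
#'
#' \code{phi_i = dihedral(C_(i-1), N_i, CA_i, C_i)},
#' \code{psi_i = dihedral(N_i, CA_i, C_i, N_(i+1))}, IUPAC sign convention,
#' degrees in (-180, 180]. \code{phi} is undefined (NA) for the first
#' residue and \code{psi} for the last.
#'
#' @param conf \code{dmd_conformation}.
#' @return data.frame: residue (construct numbering), phi, psi.
#' @export
compute_torsions <- function(conf) {
  topo <- conf$topo
  xyz <- array(conf$xyz, c(nrow(conf$xyz), 3, 1))
  tt <- torsions_from_xyz(xyz, topo)
  data.frame(residue = seq_len(topo$n_res) + topo$seq$offset - 1L,
             phi = tt$phi[1, ], psi = tt$psi[1, ])
}

#' Default alpha-helical torsion window
#'
#' Open intervals bracketing the canonical alpha basin:
#' phi in (-100, -30), psi in (-80, -5) degrees.
#'
#' @return list with \code{phi} and \code{psi} interval endpoints.
#' @export
helical_window <- function() list(phi = c(-100, -30), psi = c(-80, -5))

#' Is a (phi, psi) pair alpha-helical?
#'
#' TRUE iff both angles fall strictly inside the open helical window.
#' Undefined (NA) angles are not helical.
#'
#' @param phi,psi angles in degrees; vectorised.
#' @param window torsion window (default \code{\link{helical_window}}).
#' @return logical vector.
#' @export
assign_helical <- function(phi, psi, window = helical_window()) {
  h <- phi > window$phi[1] & phi < window$phi[2] &
    psi > window$psi[1] & psi < window$psi[2]
  h[is.na(h)] <- FALSE
  h
}

# n_frames x n_res logical matrix of helical states
helical_states <- function(ens, window = helical_window()) {
  ens <- ensure_torsions(ens)
  matrix(assign_helical(as.vector(ens$phi), as.vector(ens$psi), window),
         nrow(ens$phi), ncol(ens$phi))
}

#' Per-residue helical propensity profile
#'
#' For each residue, the exact fraction of ensemble frames whose (phi, psi)
#' falls inside the helical torsion window.
#'
#' @param ens \code{temperature_ensemble}.
#' @param window torsion window (default \code{\link{helical_window}}).
#' @return object of class \code{propensity_profile}: data.frame with
#'   \code{residue} (construct numbering) and \code{propensity}; attributes
#'   \code{n_frames}, \code{temperature}, \code{offset}.
#' @export
propensity_profile <- function(ens, window = helical_window()) {
  stopifnot(n_frames(ens) >= 1)
  h <- helical_states(ens, window)
  prof <- data.frame(residue = seq_len(ncol(h)) + ens$offset - 1L,
                     propensity = colMeans(h))
  structure(prof, class = c("propensity_profile", "data.frame"),
            n_frames = nrow(h), temperature = ens$temperature,
            offset = ens$offset)
}

#' Per-frame continuous-helix run map
#'
#' For every frame, the maximal runs of consecutive helical residues of
#' length at least \code{min_run}, in construct numbering.
#'
#' @param ens \code{temperature_ensemble}.
#' @param min_run minimum run length kept (default 4, about one helical
#'   turn).
#' @param window torsion window.
#' @return object of class \code{helix_run_map}: data.frame with
#'   \code{frame}, \code{start}, \code{end}; attributes \code{n_frames},
#'   \code{n_res}, \code{min_run}, \code{offset}, \code{temperature}.
#' @export
helix_run_map <- function(ens, min_run = 4L, window = helical_window()) {
  stopifnot(min_run >= 1L)
  h <- helical_states(ens, window)
  off <- ens$offset - 1L
  rows <- vector("list", nrow(h))
  for (f in seq_len(nrow(h))) {
    r <- rle(h[f, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (any(keep)) {
      rows[[f]] <- data.frame(frame = f, start = starts[keep] + off,
                              end = ends[keep] + off)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(frame = integer(0), start = integer(0),
                                      end = integer(0))
  structure(out, class = c("helix_run_map", "data.frame"),
            n_frames = nrow(h), n_res = ncol(h), min_run = min_run,
            offset = ens$offset, temperature = ens$temperature)
}

rg_of_coords <- function(xyz) {
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Radius of gyration (CA-only)
#'
#' Root-mean-squared Euclidean distance of the alpha-carbon beads from their
#' unweighted geometric centre.
#'
#' @param conf \code{dmd_conformation}, or a plain coordinate matrix whose
#'   rows are already CA positions.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(conf) {
  if (inherits(conf, "dmd_conformation")) {
    ca <- conf$topo$beads$id[conf$topo$beads$kind == "CA"]
    xyz <- conf$xyz[ca, , drop = FALSE]
  } else {
    xyz <- conf
  }
  stopifnot(nrow(xyz) >= 1)
  rg_of_coords(xyz)
}

#' Density-of-states surface over (Rg, E)
#'
#' 2-D histogram of the ensemble over radius of gyration and potential
#' energy; \code{P} is the per-bin relative density (sums to 1 over occupied
#' bins) and \code{DoS = -k T ln P} with k = 1, defined only where P > 0.
#'
#' @param ens \code{temperature_ensemble} whose observables carry Rg and E.
#' @param temperature reduced temperature (defaults to the ensemble's).
#' @param n_bins_rg,n_bins_e number of equal-width bins per axis (default
#'   20).
#' @return object of class \code{dos_surface}: list with \code{rg_breaks},
#'   \code{e_breaks}, \code{P}, \code{dos} (both n_bins_rg x n_bins_e),
#'   \code{temperature}.
#' @export
dos_surface <- function(ens, temperature = ens$temperature,
                        n_bins_rg = 20L, n_bins_e = 20L) {
  stopifnot(n_frames(ens) >= 1, temperature > 0,
            all(c("Rg", "E") %in% names(ens$obs)))
  rg <- ens$obs$Rg
  e <- ens$obs$E
  axis_breaks <- function(x, nb, label) {
    if (diff(range(x)) == 0) {
      warning("degenerate ", label, " range; using a single bin")
      c(x[1] - 0.5, x[1] + 0.5)
    } else {
      seq(min(x), max(x), length.out = nb + 1L)
    }
  }
  rb <- axis_breaks(rg, n_bins_rg, "Rg")
  eb <- axis_breaks(e, n_bins_e, "E")
  ri <- findInterval(rg, rb, rightmost.closed = TRUE)
  ei <- findInterval(e, eb, rightmost.closed = TRUE)
  counts <- matrix(0, length(rb) - 1L, length(eb) - 1L)
  for (k in seq_along(ri)) {
    counts[ri[k], ei[k]] <- counts[ri[k], ei[k]] + 1
  }
  P <- counts / sum(counts)
  dos <- matrix(NA_real_, nrow(P), ncol(P))
  occ <- P > 0
  dos[occ] <- -temperature * log(P[occ])
  structure(list(rg_breaks = rb, e_breaks = eb, counts = counts, P = P,
                 dos = dos, temperature = temperature),
            class = "dos_surface")
}

#' @export
print.dos_surface <- function(x, ...) {
  cat(sprintf("<dos_surface> %d x %d bins (%d occupied), T = %g\n",
              nrow(x$P), ncol(x$P), sum(x$P > 0), x$temperature))
  invisible(x)
}

# Ramachandran region predicates (degrees); all intervals open
rama_regions <- function(window = helical_window()) {
  list(
    helical = function(phi, psi) assign_helical(phi, psi, window),
    extended = function(phi, psi) phi > -180 & phi < -60 & psi > 60 & psi < 180,
    AT1 = function(phi, psi) phi > -100 & phi < -80 & psi > -30 & psi < 30,
    AT2 = function(phi, psi) phi > -180 & phi < -50 & psi > -170 & psi < -70,
    AG = function(phi, psi) phi > 0,
    forbidden = function(phi, psi) phi > -50 & phi < 50
  )
}

#' Ramachandran region occupancies
#'
#' Fractions of defined (phi, psi) points falling in the named torsion
#' regions: the helical window; the extended basin; the two
#' helix-extended transition corridors AT1 (phi in (-100, -80), psi in
#' (-30, 30)) and AT2 (phi in (-180, -50), psi in (-170, -70)); the
#' positive-phi half-plane AG; and the near-phi-zero band (phi in (-50, 50))
#' that is sterically forbidden for non-glycine residues. Glycine residues
#' are tallied separately.
#'
#' @param ens \code{temperature_ensemble}.
#' @param window helical torsion window.
#' @return object of class \code{rama_occupancy}: list with \code{fractions}
#'   (non-Gly), \code{gly} (same regions over Gly residues; NA when the
#'   sequence has no glycine), \code{n_points}, \code{n_gly}.
#' @export
ramachandran_occupancy <- function(ens, window = helical_window()) {
  ens <- ensure_torsions(ens)
  gly <- ens$aa == "G"
  phi <- as.vector(ens$phi)
  psi <- as.vector(ens$psi)
  is_gly <- rep(gly, each = nrow(ens$phi))
  ok <- !is.na(phi) & !is.na(psi)
  regs <- rama_regions(window)
  frac <- function(sel) {
    if (!any(sel)) return(stats::setNames(rep(NA_real_, length(regs)),
                                          names(regs)))
    vapply(regs, function(f) mean(f(phi[sel], psi[sel])), numeric(1))
  }
  structure(list(fractions = frac(ok & !is_gly),
                 gly = frac(ok & is_gly),
                 n_points = sum(ok & !is_gly), n_gly = sum(ok & is_gly)),
            class = "rama_occupancy")
}

#' @export
print.rama_occupancy <- function(x, ...) {
  cat("<rama_occupancy> non-Gly fractions:\n")
  print(round(x$fractions, 4))
  if (!is.na(x$gly[1])) {
    cat("Gly fractions:\n")
    print(round(x$gly, 4))
  }
  invisible(x)
}
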