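# Event primitives of discrete molecular dynamics, exposed at the R level.
# Between events every bead moves ballistically; the next event for a pair is
# the earliest positive root of |r_ij + v_ij t| = R over all reachable shell
# boundaries. These closed-form primitives are the reference semantics of the
# compiled engine and are used directly in tests.

#' Step potential
#'
#' A piecewise-constant radial pair potential: strictly increasing shell
#' radii \code{radii}, with \code{energies[k]} the energy on the open
#' interval below \code{radii[k]} (energy 0 beyond the outermost shell).
#' \code{energies[1] = Inf} encodes the hard core.
#'
#' @param radii strictly increasing shell radii (Angstrom).
#' @param energies energies below each radius; same length as \code{radii}.
#' @return object of class \code{step_potential}.
#' @examples
#' # hard core at 2.5 A with a square well of depth 1 out to 4 A
#' step_potential(c(2.5, 4), c(Inf, -1))
#' @export
step_potential <- function(radii, energies) {
  stopifnot(length(radii) == length(energies), length(radii) >= 1,
            all(diff(radii) > 0), all(radii > 0))
  structure(list(radii = radii, energies = energies),
            class = "step_potential")
}

# potential value at distance d
step_energy_at <- function(pot, d) {
  k <- findInterval(d, pot$radii) + 1L  # shell index; length+1 = outside
  e <- c(pot$energies, 0)
  e[k]
}

#' Predict the next boundary-crossing event for a free-flying pair
#'
#' @param xi,xj positions (length-3) of the two beads.
#' @param vi,vj velocities.
#' @param pot \code{step_potential} acting between them.
#' @return NULL if no boundary is reachable, else a list with \code{time}
#'   (time from now, > 0), \code{radius} (the boundary), \code{inward}
#'   (logical: crossing towards smaller separation), and \code{shell}
#'   (index of the boundary in \code{pot$radii}).
#' @export
next_pair_event <- function(xi, xj, vi, vj, pot) {
  dr <- xj - xi
  dv <- vj - vi
  r2 <- sum(dr * dr)
  v2 <- sum(dv * dv)
  if (v2 == 0) return(NULL)
  b <- sum(dr * dv)
  radii2 <- pot$radii^2

  below <- which(radii2 < r2)
  above <- which(radii2 > r2)
  t_in <- Inf
  k_in <- NA_integer_
  if (length(below) > 0L && b < 0) {
    k <- below[length(below)]
    disc <- b * b - v2 * (r2 - radii2[k])
    if (disc > 0) {
      t_in <- (-b - sqrt(disc)) / v2
      k_in <- k
    }
  }
  t_out <- Inf
  k_out <- NA_integer_
  if (length(above) > 0L) {
    k <- above[1L]
    t_out <- (-b + sqrt(b * b + v2 * (radii2[k] - r2))) / v2
    k_out <- k
  }
  if (!is.finite(t_in) && !is.finite(t_out)) return(NULL)
  if (t_in <= t_out) {
    list(time = t_in, radius = pot$radii[k_in], inward = TRUE, shell = k_in)
  } else {
    list(time = t_out, radius = pot$radii[k_out], inward = FALSE, shell = k_out)
  }
}

#' Resolve a boundary-crossing event
#'
#' Exact momentum- and energy-conserving update of a pair sitting on a shell
#' boundary. The crossing is allowed iff the radial kinetic energy
#' \code{0.5 * mu * vr^2} exceeds the energy step \code{dU}
#' (mu = reduced mass); otherwise the pair reflects elastically
#' (\code{vr -> -vr}). Tangential velocities are unchanged.
#'
#' @param xi,xj positions at the boundary.
#' @param vi,vj velocities.
#' @param dU energy step for the attempted crossing (energy after minus
#'   energy before); use \code{Inf} for a hard wall.
#' @param mi,mj masses (default 1).
#' @return list with updated \code{vi}, \code{vj} and logical \code{crossed}.
#' @export
resolve_event <- function(xi, xj, vi, vj, dU, mi = 1, mj = 1) {
  dr <- xj - xi
  r <- vnorm(dr)
  rhat <- dr / r
  dv <- vj - vi
  vr <- sum(dv * rhat)
  mu <- mi * mj / (mi + mj)
  ke_r <- 0.5 * mu * vr * vr
  if (ke_r > dU) {
    vr_new <- sign(vr) * sqrt(vr * vr - 2 * dU / mu)
    crossed <- TRUE
  } else {
    vr_new <- -vr
    crossed <- FALSE
  }
  dvr <- vr_new - vr
  list(vi = vi - (mu / mi) * dvr * rhat,
       vj = vj + (mu / mj) * dvr * rhat,
       crossed = crossed)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each component is Normal(0, sqrt(T/m)) in reduced units (k = 1). This is
#' the redraw applied by the Andersen-style thermostat at ghost collisions.
#'
#' @param n number of beads.
#' @param temperature reduced temperature.
#' @param mass bead mass (default 1).
#' @return n x 3 velocity matrix.
#' @export
draw_mb_velocities <- function(n, temperature, mass = 1) {
  matrix(stats::rnorm(3L * n, sd = sqrt(temperature / mass)), n, 3)
}
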