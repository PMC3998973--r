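# Low-level 3D geometry: cross products, dihedrals, internal-coordinate
# chain construction. All distances in Angstrom, all angles in degrees at the
# interface (radians internally).

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles in degrees to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped to (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

#' Signed dihedral angle of four points
#'
#' Right-handed IUPAC sign convention: looking from \code{p2} towards
#' \code{p3}, a clockwise rotation of the far bond relative to the near bond
#' is positive.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return dihedral angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  wrap_angle(-rad2deg(atan2(sum(m1 * n2), sum(n1 * n2))))
}

# Place atom D given three predecessors A, B, C, the bond length |C-D|, the
# bond angle B-C-D and the torsion A-B-C-D (NeRF construction). The sign
# convention matches dihedral_angle(): dihedral_angle(a, b, c, result) equals
# `torsion`.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  c + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

# Canonical peptide internal coordinates (Angstrom / degrees). Bond windows in
# the stepwise force field are centred on these values.
peptide_geometry <- function() {
  list(
    b_n_ca  = 1.46,  # N-CA bond
    b_ca_c  = 1.53,  # CA-C bond
    b_c_n   = 1.33,  # C-N peptide bond
    b_ca_cb = 1.53,  # CA-CB bond
    a_n_ca_c  = 111.0,   # backbone angle at CA
    a_ca_c_n  = 116.6,   # angle at C
    a_c_n_ca  = 121.9,   # angle at N
    a_n_ca_cb = 110.5,   # CB placement angle
    t_omega   = 180.0,   # trans peptide bond
    t_cb_improper = -120.0  # improper C-N-CA-CB torsion fixing L-chirality
  )
}

# Build backbone (+CB) coordinates for a chain from per-residue (phi, psi).
# `has_cb` is a logical vector (FALSE for Gly). phi[1] and psi[n] are unused.
# Returns a matrix with one row per bead in residue-major order
# (N, CA, C[, CB]).
build_chain_coords <- function(phi, psi, has_cb) {
  g <- peptide_geometry()
  n_res <- length(has_cb)
  stopifnot(length(phi) == n_res, length(psi) == n_res)
  ncoord <- matrix(NA_real_, n_res, 3)
  cacoord <- matrix(NA_real_, n_res, 3)
  ccoord <- matrix(NA_real_, n_res, 3)
  ncoord[1L, ] <- c(0, 0, 0)
  cacoord[1L, ] <- c(g$b_n_ca, 0, 0)
  ang <- deg2rad(g$a_n_ca_c)
  ccoord[1L, ] <- cacoord[1L, ] +
    c(-g$b_ca_c * cos(ang), g$b_ca_c * sin(ang), 0)
  if (n_res > 1L) {
    for (i in seq_len(n_res - 1L)) {
      ncoord[i + 1L, ] <- place_atom(ncoord[i, ], cacoord[i, ], ccoord[i, ],
                                     g$b_c_n, g$a_ca_c_n, psi[i])
      cacoord[i + 1L, ] <- place_atom(cacoord[i, ], ccoord[i, ], ncoord[i + 1L, ],
                                      g$b_n_ca, g$a_c_n_ca, g$t_omega)
      ccoord[i + 1L, ] <- place_atom(ccoord[i, ], ncoord[i + 1L, ], cacoord[i + 1L, ],
                                     g$b_ca_c, g$a_n_ca_c, phi[i + 1L])
    }
  }
  out <- matrix(NA_real_, 3L * n_res + sum(has_cb), 3)
  row <- 1L
  for (i in seq_len(n_res)) {
    out[row, ] <- ncoord[i, ]; row <- row + 1L
    out[row, ] <- cacoord[i, ]; row <- row + 1L
    out[row, ] <- ccoord[i, ]; row <- row + 1L
    if (has_cb[i]) {
      out[row, ] <- place_atom(ccoord[i, ], ncoord[i, ], cacoord[i, ],
                               g$b_ca_cb, g$a_n_ca_cb, g$t_cb_improper)
      row <- row + 1L
    }
  }
  out
}
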