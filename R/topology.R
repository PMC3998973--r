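# Coarse-grained chain topology: four beads per residue (N, CA, C, CB;
# glycine lacks CB). Covalent bonds and 1-3 pseudo-bonds are infinite square
# wells [d_min, d_max] centred on canonical peptide geometry; an additional
# CA(i)-CA(i+1) pseudo-bond keeps the peptide bond trans. All beads have
# mass 1 (reduced units): kinetics are not interpreted physically.

BEAD_KINDS <- c("N", "CA", "C", "CB")

# 1-3 reference distances are measured once from a template dipeptide built
# with the same internal coordinates as every chain, so a freshly built
# conformation satisfies all windows exactly.
template_13_distances <- function() {
  g <- peptide_geometry()
  xyz <- build_chain_coords(phi = c(180, 180), psi = c(180, 180),
                           has_cb = c(TRUE, TRUE))
  # rows: 1 N1, 2 CA1, 3 C1, 4 CB1, 5 N2, 6 CA2, 7 C2, 8 CB2
  d <- function(i, j) vnorm(xyz[i, ] - xyz[j, ])
  list(
    n_c    = d(1, 3),  # N(i)-C(i), fixes N-CA-C angle
    n_cb   = d(1, 4),  # N(i)-CB(i)
    c_cb   = d(3, 4),  # C(i)-CB(i)
    ca_n1  = d(2, 5),  # CA(i)-N(i+1), fixes CA-C-N angle
    c_ca1  = d(3, 6),  # C(i)-CA(i+1), fixes C-N-CA angle
    ca_ca1 = d(2, 6),  # CA(i)-CA(i+1), fixes omega trans
    bonds = c(n_ca = g$b_n_ca, ca_c = g$b_ca_c, c_n = g$b_c_n,
              ca_cb = g$b_ca_cb)
  )
}

#' Build a coarse-grained chain topology from a sequence
#'
#' Four beads per residue (N, CA, C, CB; glycine has no CB), unit masses,
#' covalent bonds and angle-fixing pseudo-bonds as hard distance windows.
#'
#' @param seq a \code{residue_seq} (or a string accepted by
#'   \code{\link{residue_seq}}).
#' @param params force-field parameter set (see \code{\link{ff_params}});
#'   supplies the relative window half-widths for bonds and pseudo-bonds.
#' @return object of class \code{chain_topology}: list with \code{beads}
#'   (data.frame: id, res, kind), \code{bonds} (data.frame: i, j, dmin, dmax,
#'   type), \code{seq}, \code{n_res}, \code{n_beads}.
#' @examples
#' topo <- build_topology(residue_seq("GAA"))
#' topo$n_beads  # 11: glycine contributes 3 beads, alanine 4
#' @export
build_topology <- function(seq, params = ff_params()) {
  if (!inherits(seq, "residue_seq")) seq <- residue_seq(seq)
  n_res <- length(seq$aa)
  has_cb <- seq$aa != "G"

  kind <- unlist(lapply(seq_len(n_res), function(i) {
    if (has_cb[i]) c("N", "CA", "C", "CB") else c("N", "CA", "C")
  }))
  res <- rep.int(seq_len(n_res), ifelse(has_cb, 4L, 3L))
  beads <- data.frame(id = seq_along(kind), res = res, kind = kind,
                      stringsAsFactors = FALSE)
  idx <- function(r, k) beads$id[beads$res == r & beads$kind == k]

  tpl <- template_13_distances()
  hw_b <- params$bond_halfwidth    # relative half-width, covalent bonds
  hw_p <- params$pseudo_halfwidth  # relative half-width, pseudo-bonds
  rows <- list()
  add <- function(i, j, d0, hw, type) {
    rows[[length(rows) + 1L]] <<- data.frame(
      i = i, j = j, dmin = d0 * (1 - hw), dmax = d0 * (1 + hw),
      type = type, stringsAsFactors = FALSE)
  }
  for (r in seq_len(n_res)) {
    nN <- idx(r, "N"); nCA <- idx(r, "CA"); nC <- idx(r, "C")
    add(nN, nCA, tpl$bonds[["n_ca"]], hw_b, "bond")
    add(nCA, nC, tpl$bonds[["ca_c"]], hw_b, "bond")
    add(nN, nC, tpl$n_c, hw_p, "pseudo")
    if (has_cb[r]) {
      nCB <- idx(r, "CB")
      add(nCA, nCB, tpl$bonds[["ca_cb"]], hw_b, "bond")
      add(nN, nCB, tpl$n_cb, hw_p, "pseudo")
      add(nC, nCB, tpl$c_cb, hw_p, "pseudo")
    }
    if (r < n_res) {
      mN <- idx(r + 1L, "N"); mCA <- idx(r + 1L, "CA")
      add(nC, mN, tpl$bonds[["c_n"]], hw_b, "bond")
      add(nCA, mN, tpl$ca_n1, hw_p, "pseudo")
      add(nC, mCA, tpl$c_ca1, hw_p, "pseudo")
      add(nCA, mCA, tpl$ca_ca1, hw_p, "pseudo")  # omega kept trans
    }
  }
  bonds <- do.call(rbind, rows)
  stopifnot(all(bonds$dmin > 0), all(bonds$dmin < bonds$dmax))

  structure(list(beads = beads, bonds = bonds, seq = seq,
                 n_res = n_res, n_beads = nrow(beads),
                 masses = rep(1, nrow(beads))),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("<chain_topology> %s: %d residues, %d beads, %d distance windows\n",
              x$seq$name, x$n_res, x$n_beads, nrow(x$bonds)))
  invisible(x)
}

# id of the bead of `kind` in residue r (NA if absent, e.g. Gly CB)
bead_index <- function(topo, r, kind) {
  hit <- topo$beads$id[topo$beads$res == r & topo$beads$kind == kind]
  if (length(hit) == 0L) NA_integer_ else hit
}

# n_res x 4 matrix of bead ids by kind (NA where absent)
bead_index_matrix <- function(topo) {
  m <- matrix(NA_integer_, topo$n_res, 4,
              dimnames = list(NULL, BEAD_KINDS))
  for (k in BEAD_KINDS) {
    sel <- topo$beads$kind == k
    m[topo$beads$res[sel], k] <- topo$beads$id[sel]
  }
  m
}

#' Construct a conformation object
#'
#' @param topo \code{chain_topology}.
#' @param xyz numeric n_beads x 3 matrix (Angstrom).
#' @param vel numeric n_beads x 3 matrix (reduced units); default zero.
#' @param time timestamp in reduced time units.
#' @param energy potential energy (reduced units) or NA if not yet evaluated.
#' @return object of class \code{dmd_conformation}.
#' @export
conformation <- function(topo, xyz, vel = NULL, time = 0, energy = NA_real_) {
  stopifnot(inherits(topo, "chain_topology"),
            is.matrix(xyz), nrow(xyz) == topo$n_beads, ncol(xyz) == 3,
            all(is.finite(xyz)))
  if (is.null(vel)) vel <- matrix(0, topo$n_beads, 3)
  stopifnot(nrow(vel) == topo$n_beads, ncol(vel) == 3, all(is.finite(vel)))
  structure(list(topo = topo, xyz = xyz, vel = vel,
                 time = time, energy = energy),
            class = "dmd_conformation")
}

#' @export
print.dmd_conformation <- function(x, ...) {
  cat(sprintf("<dmd_conformation> %d beads, t = %g tu, E = %s\n",
              nrow(x$xyz), x$time,
              if (is.na(x$energy)) "unset" else format(x$energy)))
  invisible(x)
}

#' Build a fully extended starting conformation
#'
#' All backbone phi/psi torsions set to 180 degrees; velocities zero. By
#' construction the result satisfies every bond window exactly.
#'
#' @param topo \code{chain_topology}.
#' @return \code{dmd_conformation}.
#' @export
build_extended <- function(topo) {
  n <- topo$n_res
  xyz <- build_chain_coords(phi = rep(180, n), psi = rep(180, n),
                           has_cb = topo$seq$aa != "G")
  conformation(topo, xyz)
}

#' Build an ideal alpha-helix conformation
#'
#' Internal residues at (phi, psi) = (-57, -47) degrees.
#'
#' @param topo \code{chain_topology}.
#' @return \code{dmd_conformation}.
#' @export
build_ideal_helix <- function(topo) {
  n <- topo$n_res
  xyz <- build_chain_coords(phi = rep(-57, n), psi = rep(-47, n),
                           has_cb = topo$seq$aa != "G")
  conformation(topo, xyz)
}
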