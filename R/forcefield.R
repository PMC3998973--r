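# Stepwise (square-well) force field. Every bead pair resolves to exactly one
# of: excluded (bonded/pseudo-bonded), hard window (bond), or a nonbonded step
# potential (hard core + optional single attractive shell). Helix-stabilising
# i->i+4 hydrogen-bond-like wells act between C(i) and N(i+4) and count only
# while a conjunction of gating distance windows holds (span, chirality and
# per-torsion gates) -- a stepwise, multi-body stand-in for the angular
# dependence of a backbone hydrogen bond. Small unconditional wells inside
# the torsion-gate windows provide the helical dihedral bias that makes
# nucleation kinetically accessible.

#' Load force-field parameters
#'
#' Parameters are a flat key-value text file (\code{key = value}, \code{#}
#' comments). With no argument, the packaged default parameter set is loaded.
#'
#' @param path path to a parameter file, or NULL for the packaged default.
#' @param overrides named list of values overriding those read from the file.
#' @return named list of class \code{ff_params}; carries the source file
#'   checksum as attribute \code{checksum}.
#' @export
ff_params <- function(path = NULL, overrides = list()) {
  if (is.null(path)) {
    path <- system.file("extdata", "forcefield_default.txt",
                        package = "rexdmd", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("no such force-field file: ", path)
  kv <- read_keyvalue(path)
  num <- suppressWarnings(lapply(kv, as.numeric))
  bad <- names(kv)[vapply(num, function(v) any(is.na(v)), logical(1))]
  if (length(bad) > 0L) stop("non-numeric force-field value for key: ", bad[1L])
  p <- num
  for (k in names(overrides)) p[[k]] <- overrides[[k]]
  attr(p, "checksum") <- unname(tools::md5sum(path))
  attr(p, "source") <- path
  class(p) <- "ff_params"
  p
}

ff_get <- function(params, key, default = NULL) {
  if (!is.null(params[[key]])) return(params[[key]])
  if (!is.null(default)) return(default)
  stop("missing force-field parameter: ", key)
}

# helix-propensity weight of one-letter code(s); w(Ala) = 1 by convention
hb_weight <- function(params, aa) {
  vapply(aa, function(a) ff_get(params, paste0("w_", a)), numeric(1))
}

# steric core radius for a bead-kind pair (symmetric lookup)
sigma_lookup <- function(params, k1, k2) {
  key1 <- paste0("sigma_", k1, "_", k2)
  key2 <- paste0("sigma_", k2, "_", k1)
  if (!is.null(params[[key1]])) return(params[[key1]])
  if (!is.null(params[[key2]])) return(params[[key2]])
  stop("missing steric core parameter for bead-kind pair ", k1, "-", k2)
}

#' Compile a force field for a chain topology
#'
#' Resolves every bead pair to excluded / bonded window / nonbonded step
#' potential, and instantiates the sequence-dependent i->i+4 hydrogen-bond
#' rules with depth \code{hb_eps * w(aa_i) * w(aa_i+4)} (weights normalised
#' to w(Ala) = 1). Each rule is gated by distance windows that pin the
#' bridged torsions to the right-handed alpha basin (see the comments in the
#' source for the geometry of the gates).
#'
#' @param topo \code{chain_topology}.
#' @param params \code{ff_params}.
#' @return object of class \code{dmd_forcefield}.
#' @export
compile_forcefield <- function(topo, params = ff_params()) {
  stopifnot(inherits(topo, "chain_topology"))
  n <- topo$n_beads
  beads <- topo$beads

  # pair class: 0 excluded (self/bonded/pseudo), 1 plain nonbonded,
  # 2 hydrogen-bond member pair (hard core + HB windows, no generic shell)
  cls <- matrix(1L, n, n)
  diag(cls) <- 0L
  for (r in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds$i[r]; j <- topo$bonds$j[r]
    cls[i, j] <- 0L; cls[j, i] <- 0L
  }

  # Hydrogen-bond rules: the i -> i+4 well between C(i) and N(i+4) counts
  # only while a conjunction of distance windows holds:
  #  - the CA(i)-CA(i+4) span gate;
  #  - torsion gates: the six bridged torsions phi/psi(i+1..i+3) are pinned
  #    through their equivalent 1-4 distances (d(C(m-1), C(m)) is a monotone
  #    function of cos phi(m), d(N(m), N(m+1)) of cos psi(m));
  #  - a chirality gate CB(i)-CA(i+3): 1-4 distances are mirror-even, so
  #    without a CB-based gate the left-handed mirror turn would satisfy
  #    every window (glycine acceptors fall back to the achiral
  #    CA(i+1)-CA(i+3) gate and rely on neighbouring rules for handedness).
  bm <- bead_index_matrix(topo)
  w <- hb_weight(params, topo$seq$aa)
  rules <- NULL
  members <- NULL
  if (topo$n_res >= 5L) {
    i <- seq_len(topo$n_res - 4L)
    has_cb <- !is.na(bm[i, "CB"])
    rules <- data.frame(res = i,
                        depth = ff_get(params, "hb_eps") * w[i] * w[i + 4L])
    stopifnot(all(rules$depth > 0))
    # torsion window -> gate distance windows (open intervals)
    phi_win <- c(ff_get(params, "hb_phi_lo", -100),
                 ff_get(params, "hb_phi_hi", -30))
    psi_win <- c(ff_get(params, "hb_psi_lo", -80),
                 ff_get(params, "hb_psi_hi", -5))
    dcc <- function(p) {
      xyz <- build_chain_coords(c(180, p), c(180, 180), c(TRUE, TRUE))
      vnorm(xyz[7, ] - xyz[3, ])   # C(1)..C(2)
    }
    dnn <- function(q) {
      xyz <- build_chain_coords(c(180, 180), c(q, 180), c(TRUE, TRUE))
      vnorm(xyz[5, ] - xyz[1, ])   # N(1)..N(2)
    }
    cc_win <- sort(c(dcc(phi_win[1]), dcc(phi_win[2])))
    nn_win <- sort(c(dnn(psi_win[1]), dnn(psi_win[2])))
    # chiral torsion gates: CB-involving 1-4 distances are odd in the
    # torsion sign (the 1-4 backbone distances above are mirror-even), so
    # the intersection of the even and chiral windows pins each bridged
    # torsion to the right-handed helical basin exactly
    dccb <- function(p) {
      xyz <- build_chain_coords(c(180, p), c(180, 180), c(TRUE, TRUE))
      vnorm(xyz[8, ] - xyz[3, ])   # C(1)..CB(2)
    }
    dcbn <- function(q) {
      xyz <- build_chain_coords(c(180, 180), c(q, 180), c(TRUE, TRUE))
      vnorm(xyz[5, ] - xyz[4, ])   # CB(1)..N(2)
    }
    # both chiral maps attain their maximum inside the torsion window, so
    # the gate runs from the lower endpoint value up to just above the
    # maximum; its preimage is one contiguous interval that the even gate
    # then trims to the exact torsion window
    # a slack absorbs the smearing of the distance <-> torsion map caused by
    # the finite bond/pseudo-bond windows; the mirror basin stays excluded
    # by a large margin (checked by the mirror-helix unit test)
    slack <- ff_get(params, "hb_chiral_slack", 0.15)
    chiral_win <- function(fun, win) {
      grid <- seq(win[1], win[2], length.out = 60)
      dg <- vapply(grid, fun, numeric(1))
      c(min(dg[1], dg[length(dg)]) - slack, max(dg) + slack)
    }
    ccb_win <- chiral_win(dccb, phi_win)
    cbn_win <- chiral_win(dcbn, psi_win)
    mem <- list()
    add_mem <- function(rule, a, b, lo, hi, kind) {
      mem[[length(mem) + 1L]] <<- data.frame(rule = rule, i = min(a, b),
                                             j = max(a, b), lo = lo, hi = hi,
                                             kind = kind)
    }
    for (r in i) {
      add_mem(r, bm[r, "C"], bm[r + 4L, "N"],
              ff_get(params, "hb_d_on"), ff_get(params, "hb_d_off"),
              "contact")
      add_mem(r, bm[r, "CA"], bm[r + 4L, "CA"],
              ff_get(params, "hb_gate14_lo"), ff_get(params, "hb_gate14_hi"),
              "span")
      if (has_cb[r]) {
        add_mem(r, bm[r, "CB"], bm[r + 3L, "CA"],
                ff_get(params, "hb_gate_chi_lo"),
                ff_get(params, "hb_gate_chi_hi"), "chiral")
      } else {
        add_mem(r, bm[r + 1L, "CA"], bm[r + 3L, "CA"],
                ff_get(params, "hb_gate13_lo"),
                ff_get(params, "hb_gate13_hi"), "span")
      }
      for (m in (r + 1L):(r + 3L)) {
        add_mem(r, bm[m - 1L, "C"], bm[m, "C"], cc_win[1], cc_win[2],
                "torsion")
        add_mem(r, bm[m, "N"], bm[m + 1L, "N"], nn_win[1], nn_win[2],
                "torsion")
        if (!is.na(bm[m, "CB"])) {
          add_mem(r, bm[m - 1L, "C"], bm[m, "CB"], ccb_win[1], ccb_win[2],
                  "chiral_torsion")
          add_mem(r, bm[m, "CB"], bm[m + 1L, "N"], cbn_win[1], cbn_win[2],
                  "chiral_torsion")
        }
      }
    }
    members <- do.call(rbind, mem)
    # unique gate pairs; shared pairs must carry identical windows. Each
    # unique pair also carries an unconditional square well `base` inside its
    # window: a small helical torsion bias on the C-C / N-N gates and a
    # contact well on the C(i)-N(i+4) pair. These give nucleation a gradient
    # (individual residues are paid for visiting the helical basin before a
    # full turn assembles) and are what makes spontaneous helix formation
    # kinetically accessible.
    tw <- ff_get(params, "hb_torsion_well", 0)
    twc <- ff_get(params, "hb_chiral_torsion_well", 0)
    cw <- ff_get(params, "hb_contact_well", 0)
    key <- paste(members$i, members$j)
    first <- !duplicated(key)
    pairs <- members[first, c("i", "j", "lo", "hi", "kind")]
    pairs$base <- ifelse(pairs$kind == "torsion", tw,
                         ifelse(pairs$kind == "chiral_torsion", twc,
                                ifelse(pairs$kind == "contact", cw, 0)))
    for (k in unique(key)) {
      sel <- key == k
      if (length(unique(members$lo[sel])) > 1L ||
          length(unique(members$hi[sel])) > 1L) {
        stop("inconsistent windows on a shared hydrogen-bond gate pair")
      }
      pr <- c(members$i[which(sel)[1L]], members$j[which(sel)[1L]])
      if (cls[pr[1L], pr[2L]] == 0L) {
        stop("hydrogen-bond member pair is excluded; chain too short?")
      }
      cls[pr[1L], pr[2L]] <- 2L; cls[pr[2L], pr[1L]] <- 2L
    }
  } else {
    pairs <- NULL
  }

  # steric cores (local pairs scaled down to keep the torsion landscape open)
  kind_i <- beads$kind
  res_i <- beads$res
  sig_kind <- matrix(0, 4, 4, dimnames = list(BEAD_KINDS, BEAD_KINDS))
  for (a in BEAD_KINDS) for (b in BEAD_KINDS) {
    sig_kind[a, b] <- sigma_lookup(params, a, b)
  }
  sigma <- sig_kind[kind_i, kind_i]
  local_scale <- ff_get(params, "local_sigma_scale", 1)
  local <- abs(outer(res_i, res_i, "-")) <= 1L
  sigma[local] <- sigma[local] * local_scale
  sigma[cls == 0L] <- 0

  # attractive shell: generic shallow well for plain nonbonded, nonlocal
  # pairs; deeper CB-CB hydrophobic well with per-residue scale
  well_r <- matrix(0, n, n)
  well_depth <- matrix(0, n, n)
  nb_w <- ff_get(params, "nb_well_width", 0)
  nb_d <- ff_get(params, "nb_well_depth", 0)
  plain <- cls == 1L & !local
  if (nb_w > 0 && nb_d != 0) {
    well_r[plain] <- sigma[plain] + nb_w
    well_depth[plain] <- nb_d
  }
  cb_r <- ff_get(params, "cb_well_r", 0)
  cb_d <- ff_get(params, "cb_well_depth", 0)
  if (cb_r > 0 && cb_d != 0) {
    hsc <- vapply(topo$seq$aa, function(a) {
      ff_get(params, paste0("hscale_", a), 1)
    }, numeric(1))
    is_cb <- kind_i == "CB"
    cbpair <- outer(is_cb, is_cb, "&") & plain
    well_r[cbpair] <- cb_r
    scl <- outer(hsc[res_i], hsc[res_i], "*")
    well_depth[cbpair] <- cb_d * scl[cbpair]
  }

  structure(list(topo = topo, params = params, cls = cls,
                 sigma = sigma, well_r = well_r, well_depth = well_depth,
                 hb = rules, hb_members = members, hb_pairs = pairs,
                 hex = ff_get(params, "hex", 0.1),
                 checksum = attr(params, "checksum")),
            class = "dmd_forcefield")
}

#' @export
print.dmd_forcefield <- function(x, ...) {
  cat(sprintf("<dmd_forcefield> %d beads, %d HB rules, HEX = %g, checksum %s\n",
              x$topo$n_beads, if (is.null(x$hb)) 0L else nrow(x$hb),
              x$hex, substr(x$checksum, 1, 8)))
  invisible(x)
}

# active hydrogen-bond rules for a coordinate matrix: logical vector
# (a rule is active iff every member pair sits inside its window)
hb_active <- function(ff, xyz) {
  if (is.null(ff$hb)) return(logical(0))
  m <- ff$hb_members
  d <- sqrt(rowSums((xyz[m$i, , drop = FALSE] - xyz[m$j, , drop = FALSE])^2))
  ok <- d >= m$lo & d < m$hi
  unname(as.logical(tapply(ok, factor(m$rule, levels = seq_len(nrow(ff$hb))),
                           all)))
}

#' Exact potential energy of a conformation
#'
#' Sums the shell energies of all active nonbonded pairs plus all active
#' (gated) hydrogen-bond wells. A hard-core overlap or a violated bond window
#' yields \code{+Inf} (invalid state).
#'
#' @param ff \code{dmd_forcefield}.
#' @param conf \code{dmd_conformation} built on the same topology.
#' @return potential energy (reduced units); \code{+Inf} for invalid states.
#' @export
potential_energy <- function(ff, conf) {
  stopifnot(inherits(ff, "dmd_forcefield"), inherits(conf, "dmd_conformation"))
  xyz <- conf$xyz
  n <- nrow(xyz)
  stopifnot(n == ff$topo$n_beads)
  d <- as.matrix(stats::dist(xyz))

  b <- ff$topo$bonds
  db <- d[cbind(b$i, b$j)]
  if (any(db < b$dmin - 1e-9 | db > b$dmax + 1e-9)) return(Inf)

  ut <- upper.tri(d)
  core <- ut & ff$sigma > 0 & d < ff$sigma
  if (any(core)) return(Inf)

  in_well <- ut & ff$well_r > 0 & d >= ff$sigma & d < ff$well_r
  e <- -sum(ff$well_depth[in_well])
  if (!is.null(ff$hb_pairs)) {
    p <- ff$hb_pairs
    dp <- d[cbind(p$i, p$j)]
    e <- e - sum(p$base[dp >= p$lo & dp < p$hi])
  }
  act <- hb_active(ff, xyz)
  if (length(act) > 0L) e <- e - sum(ff$hb$depth[act])
  e
}
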