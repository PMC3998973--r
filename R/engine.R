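# R-side driver for the compiled event engine: flattening a compiled force
# field into the engine's static-pair/boundary tables, running trajectory
# segments, and the two-stage restrained relaxation protocol.

B_WALL_LO <- 0L; B_WALL_HI <- 1L; B_STEP <- 2L; B_HB_LO <- 3L; B_HB_HI <- 4L

# Flatten a dmd_forcefield into the engine's static pair/boundary arrays.
# Optional tethers: list(idx = bead ids, anchors = matrix, halfwidth).
engine_pack <- function(ff, tethers = NULL) {
  topo <- ff$topo
  sp <- list(); bounds <- list()
  add_pair <- function(i, j, tether, blist) {
    sp[[length(sp) + 1L]] <<- c(i = i, j = j, tether = tether,
                                b0 = length(bounds), nb = length(blist))
    for (b in blist) bounds[[length(bounds) + 1L]] <<- b
    length(sp)  # 1-based static index
  }
  bnd <- function(r, type, du = 0, rule = 0L, rule2 = 0L) {
    c(r = r, type = type, du = du, rstart = rule, rcount = rule2)
  }
  for (k in seq_len(nrow(topo$bonds))) {
    b <- topo$bonds[k, ]
    add_pair(b$i, b$j, -1L,
             list(bnd(b$dmin, B_WALL_LO), bnd(b$dmax, B_WALL_HI)))
  }
  # hydrogen-bond member pairs: one static pair per unique (i, j); its lo/hi
  # window edges carry the list of rules gated by that pair
  nr <- if (is.null(ff$hb)) 0L else nrow(ff$hb)
  mem <- ff$hb_members
  edge_rules <- integer(0)
  r_mstart <- integer(nr); r_mcount <- integer(nr)
  mem_sp_flat <- integer(0); mem_lo_flat <- numeric(0); mem_hi_flat <- numeric(0)
  if (nr > 0L) {
    key <- paste(mem$i, mem$j)
    upairs <- ff$hb_pairs
    sp_of_key <- integer(nrow(upairs))
    names(sp_of_key) <- paste(upairs$i, upairs$j)
    for (k in seq_len(nrow(upairs))) {
      u <- upairs[k, ]
      rules_here <- sort(mem$rule[key == paste(u$i, u$j)]) - 1L
      sig <- ff$sigma[u$i, u$j]
      if (sig >= u$lo) stop("steric core reaches into a hydrogen-bond window")
      rstart <- length(edge_rules)
      edge_rules <- c(edge_rules, rules_here)
      # window edges carry the pair's unconditional well `base`:
      # du_in(lo) = +base, du_in(hi) = -base, so the inside of the window
      # sits at -base on top of any rule energies
      sp_of_key[k] <- add_pair(u$i, u$j, -1L, list(
        bnd(sig, B_WALL_LO),
        bnd(u$lo, B_HB_LO, du = u$base, rule = rstart,
            rule2 = length(rules_here)),
        bnd(u$hi, B_HB_HI, du = -u$base, rule = rstart,
            rule2 = length(rules_here))))
    }
    pos <- 0L
    for (r in seq_len(nr)) {
      sel <- which(mem$rule == r)
      r_mstart[r] <- pos
      r_mcount[r] <- length(sel)
      mem_sp_flat <- c(mem_sp_flat,
                       sp_of_key[paste(mem$i[sel], mem$j[sel])] - 1L)
      mem_lo_flat <- c(mem_lo_flat, mem$lo[sel])
      mem_hi_flat <- c(mem_hi_flat, mem$hi[sel])
      pos <- pos + length(sel)
    }
  }
  anchors <- matrix(0, 1, 3)
  if (!is.null(tethers)) {
    anchors <- tethers$anchors
    for (k in seq_along(tethers$idx)) {
      add_pair(tethers$idx[k], -1L, k - 1L,
               list(bnd(tethers$halfwidth, B_WALL_HI)))
    }
  }
  spm <- do.call(rbind, sp)
  bm <- do.call(rbind, bounds)
  list(sp_i = as.integer(spm[, "i"] - 1L),
       sp_j = as.integer(ifelse(spm[, "j"] < 0, -1L, spm[, "j"] - 1L)),
       sp_tether = as.integer(spm[, "tether"]),
       sp_b0 = as.integer(spm[, "b0"]), sp_nb = as.integer(spm[, "nb"]),
       b_r = as.numeric(bm[, "r"]), b_type = as.integer(bm[, "type"]),
       b_du = as.numeric(bm[, "du"]),
       b_rstart = as.integer(bm[, "rstart"]),
       b_rcount = as.integer(bm[, "rcount"]),
       edge_rules = as.integer(edge_rules),
       r_depth = if (nr > 0L) as.numeric(ff$hb$depth) else numeric(0),
       r_mstart = r_mstart, r_mcount = r_mcount,
       mem_sp = as.integer(mem_sp_flat),
       mem_lo = as.numeric(mem_lo_flat), mem_hi = as.numeric(mem_hi_flat),
       anchors = anchors,
       bnd_i = as.integer(topo$bonds$i - 1L),
       bnd_j = as.integer(topo$bonds$j - 1L),
       bnd_lo = as.numeric(topo$bonds$dmin),
       bnd_hi = as.numeric(topo$bonds$dmax))
}

engine_call <- function(conf, ff, temperature, duration, save_every, seed,
                        hex, t_start, init_velocities, tethers = NULL,
                        skin = 0.8, max_events = 2e9) {
  pk <- engine_pack(ff, tethers)
  .dmd_run_cpp(conf$xyz, conf$vel, ff$topo$masses,
               ff$cls, ff$sigma, ff$well_r, ff$well_depth,
               pk$sp_i, pk$sp_j, pk$sp_tether, pk$sp_b0, pk$sp_nb,
               pk$b_r, pk$b_type, pk$b_du,
               pk$b_rstart, pk$b_rcount, pk$edge_rules,
               pk$r_depth, pk$r_mstart, pk$r_mcount,
               pk$mem_sp, pk$mem_lo, pk$mem_hi,
               pk$anchors, pk$bnd_i, pk$bnd_j, pk$bnd_lo, pk$bnd_hi,
               temperature, hex, t_start, duration, save_every,
               as.numeric(seed), init_velocities, skin, max_events)
}

#' Run one event-driven dynamics segment
#'
#' Propagates a conformation at fixed thermostat temperature for
#' \code{duration} time units, saving frames at every global multiple of
#' \code{save_every} (excluding the start time). Bit-reproducible for a fixed
#' seed.
#'
#' @param conf starting \code{dmd_conformation}.
#' @param ff \code{dmd_forcefield}.
#' @param temperature reduced temperature (k = 1).
#' @param duration segment length (time units), > 0.
#' @param save_every frame interval (time units).
#' @param seed integer seed for the engine RNG stream.
#' @param hex Andersen heat-exchange factor (ghost-collision rate scale);
#'   0 gives strictly energy-conserving dynamics.
#' @param init_velocities draw Maxwell-Boltzmann start velocities inside the
#'   engine; default TRUE when the conformation's velocities are all zero.
#' @param max_events safety cap on the number of pair events.
#' @return object of class \code{dmd_trajectory}: \code{frames}
#'   (beads x 3 x n_frames array), \code{obs} (data.frame: frame, time,
#'   temperature, E, K, Rg), \code{final} conformation, event counts.
#' @export
run_segment <- function(conf, ff, temperature, duration, save_every,
                        seed = 1L, hex = ff$hex,
                        init_velocities = all(conf$vel == 0),
                        max_events = 2e9) {
  stopifnot(duration > 0, save_every > 0, temperature > 0 || hex == 0)
  res <- engine_call(conf, ff, temperature, duration, save_every, seed,
                     hex, t_start = conf$time,
                     init_velocities = init_velocities,
                     max_events = max_events)
  traj_from_engine(res, ff$topo, temperature, seed)
}

traj_from_engine <- function(res, topo, temperature, seed) {
  nf <- length(res$frame_t)
  rg <- numeric(nf)
  ca <- topo$beads$id[topo$beads$kind == "CA"]
  for (f in seq_len(nf)) {
    rg[f] <- rg_of_coords(res$frames[, , f, drop = FALSE][ca, , 1])
  }
  obs <- data.frame(frame = seq_len(nf), time = res$frame_t,
                    temperature = rep(temperature, nf),
                    E = res$frame_E, K = res$frame_K, Rg = rg)
  final <- conformation(topo, res$x, res$v, time = res$time,
                        energy = res$epot)
  structure(list(topo = topo, frames = res$frames, obs = obs, final = final,
                 n_events = res$n_events, n_ghosts = res$n_ghosts,
                 n_pred = res$n_pred, n_push = res$n_push,
                 n_rebuild = res$n_rebuild, seed = seed),
            class = "dmd_trajectory")
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat(sprintf("<dmd_trajectory> %d frames, %d beads, %.0f events, T = %g\n",
              nrow(x$obs), dim(x$frames)[1], x$n_events,
              x$obs$temperature[1]))
  invisible(x)
}

#' Two-stage restrained relaxation protocol
#'
#' Relaxes a (possibly strained) starting structure with two short
#' thermostatted segments: first at high heat-exchange coupling and high
#' temperature (defaults 1,000 tu, HEX = 10, T = 0.7), then at low coupling
#' and low temperature (1,000 tu, HEX = 0.1, T = 0.5). CA and CB beads are
#' restrained by flat-bottom tethers (half-width 0.5 A) about their input
#' positions throughout.
#'
#' @param conf starting \code{dmd_conformation} (no hard-core overlaps).
#' @param ff \code{dmd_forcefield}.
#' @param protocol list of stages, each \code{list(duration, hex,
#'   temperature)}, plus \code{restraint_halfwidth}; see
#'   \code{\link{minimize_protocol}}.
#' @param seed engine RNG seed.
#' @return relaxed \code{dmd_conformation} with its potential energy set.
#' @export
minimize <- function(conf, ff, protocol = minimize_protocol(), seed = 1L) {
  topo <- ff$topo
  keep <- topo$beads$kind %in% c("CA", "CB")
  tethers <- list(idx = topo$beads$id[keep],
                  anchors = conf$xyz[keep, , drop = FALSE],
                  halfwidth = protocol$restraint_halfwidth)
  cur <- conf
  sd_seed <- as.numeric(seed)
  for (st in protocol$stages) {
    res <- engine_call(cur, ff, st$temperature, st$duration,
                       save_every = st$duration, seed = sd_seed,
                       hex = st$hex, t_start = 0,
                       init_velocities = TRUE, tethers = tethers)
    cur <- conformation(topo, res$x, res$v, time = conf$time,
                        energy = res$epot)
    sd_seed <- sd_seed + 1
  }
  cur
}

#' Number of frames saved by a schedule
#'
#' Frames are recorded at every global multiple of \code{save_every} in
#' \code{(t_start, t_start + duration]}; the default production schedule
#' (1,000,000 tu, save every 200 tu) therefore yields exactly 5,000 frames
#' per replica.
#'
#' @param duration segment or run length (time units).
#' @param save_every frame interval.
#' @param t_start global start time (default 0).
#' @return integer frame count.
#' @export
schedule_frames <- function(duration, save_every, t_start = 0) {
  k0 <- floor(t_start / save_every + 1e-9) + 1
  kmax <- floor((t_start + duration) / save_every + 1e-9)
  as.integer(max(0, kmax - k0 + 1))
}

#' Default relaxation protocol parameters
#'
#' Stage 1: 1,000 tu at HEX = 10, T = 0.7. Stage 2: 1,000 tu at HEX = 0.1,
#' T = 0.5 (stage-2 duration mirrors stage 1). Restraint half-width 0.5 A.
#'
#' @return protocol list consumed by \code{\link{minimize}}.
#' @export
minimize_protocol <- function() {
  list(stages = list(list(duration = 1000, hex = 10, temperature = 0.7),
                     list(duration = 1000, hex = 0.1, temperature = 0.5)),
       restraint_halfwidth = 0.5)
}
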