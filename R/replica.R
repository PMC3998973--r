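# Temperature replica exchange: N replicas at a fixed temperature ladder,
# Metropolis temperature swaps between adjacent rungs on a fixed schedule
# (alternating even/odd adjacent pairs), velocity rescaling on accepted
# swaps, and regrouping of frames by temperature for analysis.

#' The default 8-rung temperature ladder
#'
#' @return numeric vector of 8 reduced temperatures (k = 1), strictly
#'   ascending, spaced for at least 25\% adjacent-pair exchange acceptance on
#'   chains up to ~100 residues.
#' @export
default_ladder <- function() {
  c(0.5246, 0.5451, 0.5665, 0.5886, 0.6116, 0.6355, 0.6604, 0.6862)
}

#' Metropolis acceptance probability for a temperature swap
#'
#' \code{p = min(1, exp((1/T_i - 1/T_j) (E_i - E_j)))} with k = 1.
#'
#' @param t_i,t_j rung temperatures (> 0).
#' @param e_i,e_j current potential energies of the replicas at those rungs.
#' @return acceptance probability in [0, 1]; vectorised.
#' @export
swap_probability <- function(t_i, t_j, e_i, e_j) {
  stopifnot(all(t_i > 0), all(t_j > 0))
  pmin(1, exp((1 / t_i - 1 / t_j) * (e_i - e_j)))
}

#' Stochastic Metropolis swap decision
#'
#' Accepts with probability \code{p} using the R random stream; vectorised
#' for replayed acceptance checks.
#'
#' @param p acceptance probability (or vector of probabilities).
#' @return logical vector of decisions.
#' @export
swap_decide <- function(p) stats::runif(length(p)) < p

#' Run a replica-exchange simulation
#'
#' All replicas start from the same conformation with fresh
#' Maxwell-Boltzmann velocities at their rung temperatures. Swaps are
#' attempted every \code{swap_every} time units between adjacent rungs,
#' alternating between the even-indexed pairs (1-2, 3-4, ...) and the
#' odd-indexed pairs (2-3, 4-5, ...). Temperatures (labels) are swapped;
#' velocities of swapped replicas are rescaled by sqrt(T_new/T_old). The
#' ladder multiset is invariant throughout.
#'
#' @param conf starting \code{dmd_conformation} (typically from
#'   \code{\link{minimize}}).
#' @param ff \code{dmd_forcefield}.
#' @param ladder temperature ladder (default \code{\link{default_ladder}}).
#' @param total_duration production length per replica (time units).
#' @param swap_every exchange-attempt interval (default 1,000 tu).
#' @param save_every frame interval (default 200 tu).
#' @param seed integer; seeds both the swap RNG and the per-segment engine
#'   streams.
#' @param hex Andersen heat-exchange factor (default from the force field).
#' @return object of class \code{rx_run}: per-replica trajectories (frames +
#'   observables with the temperature held at each frame), swap records,
#'   ladder, schedule, seed.
#' @export
run_rx <- function(conf, ff, ladder = default_ladder(),
                   total_duration = 1e6, swap_every = 1000,
                   save_every = 200, seed = 1L, hex = ff$hex) {
  stopifnot(length(ladder) >= 2, all(diff(ladder) > 0),
            total_duration > 0, swap_every > 0, save_every > 0)
  n_rep <- length(ladder)
  n_rounds <- floor(total_duration / swap_every)
  if (n_rounds * swap_every != total_duration) {
    stop("total_duration must be a multiple of swap_every")
  }

  # deterministic sub-streams: engine seeds and swap decisions from one seed
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state)) assign(".Random.seed", rng_state,
                                    envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)

  rung_of <- seq_len(n_rep)    # replica -> rung index
  states <- vector("list", n_rep)
  epot <- numeric(n_rep)
  for (k in seq_len(n_rep)) states[[k]] <- conf
  frames <- vector("list", n_rep)   # per replica: list of trajectory chunks
  for (k in seq_len(n_rep)) frames[[k]] <- vector("list", n_rounds)
  swaps <- vector("list", n_rounds)

  for (round in seq_len(n_rounds)) {
    for (k in seq_len(n_rep)) {
      tk <- ladder[rung_of[k]]
      seg_seed <- sample.int(.Machine$integer.max - 1L, 1L)
      tr <- run_segment(states[[k]], ff, temperature = tk,
                        duration = swap_every, save_every = save_every,
                        seed = seg_seed, hex = hex,
                        init_velocities = (round == 1L))
      if (!all(is.finite(tr$final$energy))) {
        stop("replica ", k, " diverged (non-finite energy)")
      }
      tr$obs$temperature <- rep(tk, nrow(tr$obs))
      states[[k]] <- tr$final
      epot[k] <- tr$final$energy
      frames[[k]][[round]] <- tr
    }
    # alternating adjacent-pair exchange attempts
    first <- if (round %% 2L == 1L) 1L else 2L
    att_rungs <- if (first > n_rep - 1L) integer(0) else
      seq(first, n_rep - 1L, by = 2L)
    t_att <- round * swap_every
    rec <- lapply(att_rungs, function(a) {
      ra <- which(rung_of == a)
      rb <- which(rung_of == a + 1L)
      p <- swap_probability(ladder[a], ladder[a + 1L], epot[ra], epot[rb])
      acc <- swap_decide(p)
      if (acc) {
        rung_of[c(ra, rb)] <<- c(a + 1L, a)
        states[[ra]]$vel <<- states[[ra]]$vel * sqrt(ladder[a + 1L] / ladder[a])
        states[[rb]]$vel <<- states[[rb]]$vel * sqrt(ladder[a] / ladder[a + 1L])
      }
      data.frame(time = t_att, rung_lo = a, rung_hi = a + 1L,
                 E_lo = epot[ra], E_hi = epot[rb], p = p, accepted = acc)
    })
    swaps[[round]] <- do.call(rbind, rec)
  }

  traj <- lapply(seq_len(n_rep), function(k) {
    chunks <- frames[[k]]
    obs <- do.call(rbind, lapply(chunks, `[[`, "obs"))
    obs$frame <- seq_len(nrow(obs))
    arr <- array(0, c(ff$topo$n_beads, 3, nrow(obs)))
    f0 <- 0L
    for (ch in chunks) {
      nf <- dim(ch$frames)[3]
      if (nf > 0) arr[, , f0 + seq_len(nf)] <- ch$frames
      f0 <- f0 + nf
    }
    structure(list(topo = ff$topo, frames = arr, obs = obs,
                   final = states[[k]],
                   n_events = sum(vapply(chunks, `[[`, numeric(1), "n_events")),
                   n_ghosts = sum(vapply(chunks, `[[`, numeric(1), "n_ghosts")),
                   seed = seed),
              class = "dmd_trajectory")
  })

  structure(list(trajectories = traj, swaps = do.call(rbind, swaps),
                 ladder = ladder, total_duration = total_duration,
                 swap_every = swap_every, save_every = save_every,
                 seed = seed),
            class = "rx_run")
}

#' @export
print.rx_run <- function(x, ...) {
  cat(sprintf("<rx_run> %d replicas, %g tu, %d swap attempts, mean acceptance %.3f\n",
              length(x$trajectories), x$total_duration, nrow(x$swaps),
              mean(x$swaps$accepted)))
  invisible(x)
}

#' Mean adjacent-pair swap acceptance
#'
#' @param rx an \code{rx_run}.
#' @param by_pair return per-adjacent-pair acceptance rates instead of the
#'   overall mean of attempts.
#' @return acceptance fraction(s) in [0, 1].
#' @export
swap_acceptance <- function(rx, by_pair = FALSE) {
  s <- rx$swaps
  if (by_pair) {
    tapply(s$accepted, s$rung_lo, mean)
  } else {
    mean(s$accepted)
  }
}

#' Regroup replica-exchange frames by temperature
#'
#' Each rung's ensemble collects, in time order, the frames recorded by
#' whichever replica held that temperature; every frame is assigned to
#' exactly one rung and each rung receives \code{floor(duration/save_every)}
#' frames.
#'
#' @param rx an \code{rx_run}.
#' @return named list of \code{temperature_ensemble} objects, one per rung.
#' @export
demux_by_temperature <- function(rx) {
  ladder <- rx$ladder
  expected <- floor(rx$total_duration / rx$save_every)
  out <- lapply(seq_along(ladder), function(r) {
    tk <- ladder[r]
    xyz_chunks <- list(); obs_chunks <- list()
    for (tr in rx$trajectories) {
      sel <- which(abs(tr$obs$temperature - tk) < 1e-12)
      if (length(sel) > 0L) {
        xyz_chunks[[length(xyz_chunks) + 1L]] <-
          tr$frames[, , sel, drop = FALSE]
        obs_chunks[[length(obs_chunks) + 1L]] <- tr$obs[sel, , drop = FALSE]
      }
    }
    obs <- do.call(rbind, obs_chunks)
    ord <- order(obs$time)
    obs <- obs[ord, , drop = FALSE]
    if (anyDuplicated(obs$time) > 0L || nrow(obs) != expected) {
      stop(sprintf("temperature bookkeeping gap at rung %d: %d frames, expected %d",
                   r, nrow(obs), expected))
    }
    n <- rx$trajectories[[1]]$topo$n_beads
    arr <- array(0, c(n, 3, nrow(obs)))
    f0 <- 0L
    for (ch in xyz_chunks) {
      nf <- dim(ch)[3]
      if (nf > 0) arr[, , f0 + seq_len(nf)] <- ch
      f0 <- f0 + nf
    }
    arr <- arr[, , ord, drop = FALSE]
    obs$frame <- seq_len(nrow(obs))
    rownames(obs) <- NULL
    temperature_ensemble(rx$trajectories[[1]]$topo, tk, arr, obs)
  })
  names(out) <- sprintf("T%.4f", ladder)
  out
}
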