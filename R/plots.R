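# Base-graphics views of the standard observables: propensity profiles with
# reference boxes, per-frame helix rasters, Ramachandran densities, DoS heat
# maps.

#' @export
plot.propensity_profile <- function(x, reference = NULL, threshold = NULL,
                                    main = NULL, ...) {
  if (is.null(main)) {
    main <- sprintf("Helical propensity (T = %g, %d frames)",
                    attr(x, "temperature"), attr(x, "n_frames"))
  }
  graphics::plot(x$residue, x$propensity, type = "n", ylim = c(0, 1),
                 xlab = "residue (construct numbering)",
                 ylab = "helical propensity", main = main, ...)
  if (!is.null(reference)) {
    for (k in seq_len(nrow(reference))) {
      graphics::rect(reference$start[k] - 0.5, 0, reference$end[k] + 0.5, 1,
                     col = grDevices::adjustcolor("darkgreen", 0.15),
                     border = NA)
    }
  }
  if (!is.null(threshold)) {
    graphics::abline(h = threshold, lty = 2, col = "grey40")
  }
  graphics::lines(x$residue, x$propensity, lwd = 2)
  invisible(x)
}

#' @export
plot.helix_run_map <- function(x, main = NULL, ...) {
  if (is.null(main)) {
    main <- sprintf("Continuous helices over frames (T = %g)",
                    attr(x, "temperature"))
  }
  off <- attr(x, "offset") - 1L
  graphics::plot(NA, xlim = c(1, attr(x, "n_frames")),
                 ylim = c(1 + off, attr(x, "n_res") + off),
                 xlab = "frame", ylab = "residue", main = main, ...)
  if (nrow(x) > 0) {
    graphics::segments(x$frame, x$start, x$frame, x$end, col = "steelblue4")
  }
  invisible(x)
}

#' @export
plot.dos_surface <- function(x, ...) {
  mids <- function(b) (b[-1] + b[-length(b)]) / 2
  z <- x$dos
  graphics::image(mids(x$rg_breaks), mids(x$e_breaks), z,
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  xlab = "Rg (A)", ylab = "E (energy units)",
                  main = sprintf("DoS = -kT ln P(Rg, E), T = %g",
                                 x$temperature), ...)
  invisible(x)
}

#' Ramachandran scatter of an ensemble
#'
#' @param ens \code{temperature_ensemble}.
#' @param ... passed to \code{plot}.
#' @return the ensemble, invisibly.
#' @export
plot_ramachandran <- function(ens, ...) {
  ens <- ensure_torsions(ens)
  phi <- as.vector(ens$phi)
  psi <- as.vector(ens$psi)
  ok <- !is.na(phi) & !is.na(psi)
  graphics::plot(phi[ok], psi[ok], pch = ".", cex = 1.5,
                 col = grDevices::adjustcolor("navy", 0.25),
                 xlim = c(-180, 180), ylim = c(-180, 180),
                 xlab = expression(phi), ylab = expression(psi),
                 main = sprintf("T = %g", ens$temperature), ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  invisible(ens)
}
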