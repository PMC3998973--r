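# Trajectory and table IO. Ensembles travel as multi-model PDB (one MODEL
# per frame; N/CA/C/CB atoms, construct numbering in the residue field) plus
# a sidecar TSV of per-frame observables written at full precision so that a
# round trip reproduces coordinates to PDB precision (1e-3 A) and the
# sidecar exactly.

AA_321 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
            G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
            M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
            S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
AA_123 <- stats::setNames(names(AA_321), AA_321)

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_obs.tsv")
}

#' Write an ensemble or trajectory as multi-model PDB + observables TSV
#'
#' @param ens \code{temperature_ensemble} or \code{dmd_trajectory} with
#'   coordinates.
#' @param path output PDB path; the observables sidecar goes to
#'   \code{<path minus extension>_obs.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(ens, path) {
  stopifnot(!is.null(ens$topo), !is.null(ens$frames) || !is.null(ens$xyz))
  arr <- if (!is.null(ens$frames)) ens$frames else ens$xyz
  topo <- ens$topo
  beads <- topo$beads
  off <- topo$seq$offset - 1L
  res3 <- AA_321[topo$seq$aa]
  nf <- dim(arr)[3]
  elem <- ifelse(beads$kind == "N", "N", "C")
  aname <- sprintf(" %-3s", beads$kind)  # columns 13-16
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- arr[, , f]
    lines <- sprintf(
      "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      beads$id, aname, res3[beads$res], beads$res + off,
      xyz[, 1], xyz[, 2], xyz[, 3], elem)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  obs <- ens$obs
  if (!is.null(obs)) write_tsv(obs, sidecar_path(path))
  invisible(path)
}

#' Read a multi-model PDB trajectory (+ sidecar) back into an ensemble
#'
#' @param path PDB written by \code{\link{write_trajectory}}.
#' @param params force-field parameters used to rebuild the topology.
#' @return \code{temperature_ensemble}.
#' @export
read_trajectory <- function(path, params = ff_params()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  resno <- at$resno[!duplicated(at$resno)]
  res3 <- at$resid[!duplicated(at$resno)]
  aa <- AA_123[res3]
  if (anyNA(aa)) stop("non-canonical residue in PDB: ", res3[is.na(aa)][1])
  seq <- residue_seq(paste(aa, collapse = ""), offset = min(resno),
                     name = tools::file_path_sans_ext(basename(path)))
  topo <- build_topology(seq, params)
  nf <- dim(pdb$xyz)[1]
  n <- nrow(at)
  if (n != topo$n_beads) stop("bead count mismatch reading ", path)
  # check atom ordering matches the topology
  if (!all(at$elety == topo$beads$kind)) {
    stop("atom ordering in ", path, " does not match N/CA/C/CB topology")
  }
  arr <- array(NA_real_, c(n, 3, nf))
  for (f in seq_len(nf)) {
    arr[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  }
  if (anyNA(arr)) stop("truncated trajectory: ", path)
  sc <- sidecar_path(path)
  obs <- NULL
  temperature <- NA_real_
  if (file.exists(sc)) {
    obs <- utils::read.delim(sc)
    if (nrow(obs) != nf) stop("sidecar frame count mismatch for ", path)
    if ("temperature" %in% names(obs)) temperature <- obs$temperature[1]
  }
  temperature_ensemble(topo, temperature, xyz = arr, obs = obs)
}

#' Write a data frame as TSV at full precision
#'
#' @param df data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (k in seq_along(out)) {
    if (is.numeric(out[[k]]) && !is.integer(out[[k]])) {
      out[[k]] <- sprintf("%.17g", out[[k]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a propensity profile as TSV
#'
#' @param profile \code{propensity_profile}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  df$temperature <- attr(profile, "temperature")
  df$n_frames <- attr(profile, "n_frames")
  write_tsv(df, path)
}
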