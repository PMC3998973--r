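# Flat key-value configuration files: `key = value`, `#` comments, blank
# lines ignored. Used for run configuration and force-field parameter files.

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (k in seq_along(lines)) {
    m <- regmatches(lines[k], regexec("^([A-Za-z0-9_.]+)[[:space:]]*=[[:space:]]*(.*)$",
                                      lines[k]))[[1L]]
    if (length(m) != 3L) stop(sprintf("malformed key-value line %d: '%s'",
                                      k, lines[k]))
    out[[m[2L]]] <- trimws(m[3L])
  }
  out
}

write_keyvalue <- function(kv, path) {
  lines <- vapply(names(kv), function(k) {
    sprintf("%s = %s", k, paste(format(kv[[k]], digits = 17), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default run configuration (the production protocol)
#'
#' Defaults reproduce the production schedule: the 8-rung default temperature
#' ladder, 1,000,000 time units total, exchange attempts every 1,000 tu,
#' frames every 200 tu (5,000 frames per replica), Andersen heat-exchange
#' factor 0.1.
#'
#' @param ... overrides for individual keys.
#' @return named list of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(
    ladder = default_ladder(),
    total_duration = 1e6,
    swap_every = 1000,
    save_every = 200,
    hex = 0.1,
    seed = 1L,
    # analysis defaults
    helix_phi = c(-100, -30),
    helix_psi = c(-80, -5),
    call_threshold = 0.20,
    call_min_len = 4L,
    call_max_gap = 0L,
    boundary_tol = 2L,
    min_overlap_frac = 0.5,
    dos_bins = c(20L, 20L),
    report_temperature = 0.5886)
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  stopifnot(cfg$total_duration > 0, cfg$swap_every > 0, cfg$save_every > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration file
#'
#' Keys mirror \code{\link{run_config}}; vector-valued keys
#' (\code{ladder}, \code{helix_phi}, \code{helix_psi}, \code{dos_bins}) are
#' whitespace-separated. Unknown keys are an error. A \code{forcefield} key
#' names a force-field parameter file (resolved relative to the config file).
#'
#' @param path config file.
#' @return list of class \code{run_config} with an extra \code{forcefield}
#'   entry when present.
#' @export
read_run_config <- function(path) {
  kv <- read_keyvalue(path)
  cfg <- run_config()
  numeric_vec <- c("ladder", "helix_phi", "helix_psi", "dos_bins")
  for (k in names(kv)) {
    if (k == "forcefield") {
      ffp <- kv[[k]]
      if (!file.exists(ffp)) {
        ffp <- file.path(dirname(path), kv[[k]])
      }
      cfg$forcefield <- ffp
    } else if (k %in% numeric_vec) {
      cfg[[k]] <- as.numeric(strsplit(kv[[k]], "[[:space:]]+")[[1L]])
    } else if (k %in% names(cfg)) {
      cfg[[k]] <- as.numeric(kv[[k]])
    } else {
      stop("unknown configuration key: ", k)
    }
  }
  stopifnot(cfg$total_duration > 0, cfg$swap_every > 0, cfg$save_every > 0)
  cfg
}
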