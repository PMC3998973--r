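# PreSMo calling: turn per-residue helical propensity profiles into called
# intervals, match them against reference annotations (boundary rule +/- a
# tolerance, or significant overlap of the shorter interval), and aggregate
# detection counts across proteins.

#' Call candidate PreSMo regions from a propensity profile
#'
#' Maximal runs of residues at or above \code{threshold}; runs separated by
#' at most \code{max_gap} sub-threshold residues are merged (gap residues
#' included in the interval); merged runs shorter than \code{min_len} are
#' dropped. Intervals are reported in construct numbering.
#'
#' @param profile \code{propensity_profile}.
#' @param threshold propensity threshold in (0, 1); default 0.20.
#' @param min_len minimum interval length (default 4).
#' @param max_gap maximum merged gap (default 0).
#' @return object of class \code{presmo_calls}: data.frame with
#'   \code{start}, \code{end}, \code{peak}, \code{mean} (propensities) and
#'   \code{temperature}.
#' @export
call_regions <- function(profile, threshold = 0.20, min_len = 4L,
                         max_gap = 0L) {
  stopifnot(threshold > 0, threshold < 1, min_len >= 1L, max_gap >= 0L)
  x <- profile$propensity
  res_no <- profile$residue
  above <- x >= threshold
  temperature <- attr(profile, "temperature")
  if (is.null(temperature)) temperature <- NA_real_

  runs <- data.frame(start = integer(0), end = integer(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge across small gaps
    if (nrow(runs) > 1L) {
      merged <- runs[1L, , drop = FALSE]
      for (k in 2:nrow(runs)) {
        gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
        if (gap <= max_gap) {
          merged$end[nrow(merged)] <- runs$end[k]
        } else {
          merged <- rbind(merged, runs[k, , drop = FALSE])
        }
      }
      runs <- merged
    }
    runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  }
  out <- data.frame(
    start = res_no[runs$start], end = res_no[runs$end],
    peak = vapply(seq_len(nrow(runs)), function(k) {
      max(x[runs$start[k]:runs$end[k]])
    }, numeric(1)),
    mean = vapply(seq_len(nrow(runs)), function(k) {
      mean(x[runs$start[k]:runs$end[k]])
    }, numeric(1)),
    temperature = rep(temperature, nrow(runs)))
  rownames(out) <- NULL
  structure(out, class = c("presmo_calls", "data.frame"),
            threshold = threshold, min_len = min_len, max_gap = max_gap)
}

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

#' Match predicted regions against reference annotations
#'
#' A reference interval is matched iff some predicted interval has both
#' boundaries within \code{boundary_tol} residues (the boundary rule), or
#' overlaps it by at least \code{min_overlap_frac} of the shorter interval
#' (the overlap rule). One predicted interval may satisfy several
#' references; assignment is greedy by overlap size with ties going to the
#' earlier reference.
#'
#' @param predicted \code{presmo_calls} (or data.frame with start/end).
#' @param reference reference annotation data.frame with start/end (construct
#'   numbering).
#' @param boundary_tol boundary tolerance in residues (default 2).
#' @param min_overlap_frac minimum overlap as a fraction of the shorter
#'   interval, in (0, 1] (default 0.5).
#' @return object of class \code{match_report}: per-reference data.frame
#'   (start, end, matched, rule, pred_start, pred_end) with attributes
#'   \code{n_reference}, \code{n_detected}, \code{fraction},
#'   \code{n_extra} (predictions matching no reference).
#' @export
match_regions <- function(predicted, reference, boundary_tol = 2L,
                          min_overlap_frac = 0.5) {
  stopifnot(boundary_tol >= 0, min_overlap_frac > 0, min_overlap_frac <= 1)
  np <- nrow(predicted)
  nr <- nrow(reference)
  ord <- order(-vapply(seq_len(nr), function(r) {
    if (np == 0L) return(0L)
    max(interval_overlap(predicted$start, predicted$end,
                         reference$start[r], reference$end[r]))
  }, integer(1)), seq_len(nr))  # greedy: biggest overlap first, ties earlier

  status <- data.frame(start = reference$start, end = reference$end,
                       matched = FALSE, rule = NA_character_,
                       pred_start = NA_integer_, pred_end = NA_integer_)
  pred_used <- rep(FALSE, np)
  for (r in ord) {
    if (np == 0L) break
    ov <- interval_overlap(predicted$start, predicted$end,
                           reference$start[r], reference$end[r])
    boundary <- abs(predicted$start - reference$start[r]) <= boundary_tol &
      abs(predicted$end - reference$end[r]) <= boundary_tol
    shorter <- pmin(predicted$end - predicted$start + 1L,
                    reference$end[r] - reference$start[r] + 1L)
    overlap_ok <- ov >= min_overlap_frac * shorter
    cand <- which(boundary | overlap_ok)
    if (length(cand) > 0L) {
      best <- cand[which.max(ov[cand])]
      status$matched[r] <- TRUE
      status$rule[r] <- if (boundary[best]) "boundary" else "overlap"
      status$pred_start[r] <- predicted$start[best]
      status$pred_end[r] <- predicted$end[best]
      pred_used[best] <- TRUE
    }
  }
  if ("name" %in% names(reference)) status <- cbind(name = reference$name,
                                                   status)
  n_det <- sum(status$matched)
  structure(status, class = c("match_report", "data.frame"),
            n_reference = nr, n_detected = n_det,
            fraction = if (nr > 0) n_det / nr else NA_real_,
            n_extra = sum(!pred_used))
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d of %d reference regions detected (%.1f%%), %d extra predictions\n",
              attr(x, "n_detected"), attr(x, "n_reference"),
              100 * attr(x, "fraction"), attr(x, "n_extra")))
  print.data.frame(x)
  invisible(x)
}

#' Aggregate detection counts over several match reports
#'
#' @param reports list of \code{match_report} objects (one per protein).
#' @return list with \code{n_reference}, \code{n_detected},
#'   \code{fraction}, \code{n_extra}. Extra (non-reference) predictions are
#'   counted but never labelled false positives.
#' @export
benchmark_summary <- function(reports) {
  stopifnot(length(reports) >= 1)
  n_ref <- sum(vapply(reports, attr, numeric(1), "n_reference"))
  if (n_ref == 0L) stop("no reference intervals in any report")
  n_det <- sum(vapply(reports, attr, numeric(1), "n_detected"))
  n_extra <- sum(vapply(reports, attr, numeric(1), "n_extra"))
  list(n_reference = n_ref, n_detected = n_det,
       fraction = n_det / n_ref, n_extra = n_extra)
}

#' Cross-temperature confirmation of called regions
#'
#' Flags each region called at one rung as confirmed when an overlapping
#' region (by the same matching rules) is also called at an adjacent rung.
#'
#' @param profiles list of \code{propensity_profile}, ordered by rung.
#' @param rung index of the reporting rung within \code{profiles}.
#' @param ... arguments passed to \code{\link{call_regions}}.
#' @return \code{presmo_calls} for the reporting rung with an extra logical
#'   column \code{confirmed}.
#' @export
call_regions_confirmed <- function(profiles, rung, ...) {
  calls <- call_regions(profiles[[rung]], ...)
  neigh <- c(rung - 1L, rung + 1L)
  neigh <- neigh[neigh >= 1L & neigh <= length(profiles)]
  confirmed <- rep(FALSE, nrow(calls))
  for (nb in neigh) {
    other <- call_regions(profiles[[nb]], ...)
    if (nrow(other) == 0L || nrow(calls) == 0L) next
    for (k in seq_len(nrow(calls))) {
      ov <- interval_overlap(other$start, other$end,
                             calls$start[k], calls$end[k])
      if (any(ov > 0L)) confirmed[k] <- TRUE
    }
  }
  calls$confirmed <- confirmed
  calls
}
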