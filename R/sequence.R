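# Amino-acid sequences and the construct numbering convention. Residues are
# numbered 1..n internally; every reported interval is shifted by
# `offset - 1` so that outputs align with the construct numbering used in
# experimental annotations (e.g. a 60-residue construct starting at 101).

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct an amino-acid sequence object
#'
#' @param seq character scalar (one-letter codes) or character vector of
#'   single letters. Canonical 20-letter alphabet only.
#' @param offset integer >= 1, the construct number of the first residue.
#' @param name optional construct name.
#' @return an object of class \code{residue_seq}: list with \code{aa}
#'   (character vector), \code{offset}, \code{name}.
#' @examples
#' residue_seq("GAA", offset = 101, name = "toy")
#' @export
residue_seq <- function(seq, offset = 1L, name = "chain") {
  if (length(seq) == 1L) {
    seq <- strsplit(seq, "")[[1L]]
  }
  seq <- toupper(as.character(seq))
  if (length(seq) == 0L) {
    stop("empty sequence")
  }
  bad <- which(!(seq %in% AA_ALPHABET))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue code '%s' at position %d",
                 seq[bad[1L]], bad[1L]))
  }
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 1L) {
    stop("offset must be an integer >= 1")
  }
  structure(list(aa = seq, offset = offset, name = as.character(name)),
            class = "residue_seq")
}

#' @export
print.residue_seq <- function(x, ...) {
  cat(sprintf("<residue_seq> %s: %d residues, construct numbering %d-%d\n",
              x$name, length(x$aa), x$offset, x$offset + length(x$aa) - 1L))
  cat(" ", paste(x$aa, collapse = ""), "\n")
  invisible(x)
}

#' @export
length.residue_seq <- function(x) length(x$aa)

#' Read construct sequences from a FASTA file
#'
#' The first whitespace-separated word of each header is the construct name.
#' An optional \code{offset=N} token anywhere in the header sets the construct
#' numbering of the first residue (default 1).
#'
#' @param path FASTA file.
#' @return a list of \code{residue_seq} objects, named by construct.
#' @export
read_fasta_seqs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             whole.header = TRUE)
  if (length(recs) == 0L) stop("empty FASTA: ", path)
  out <- lapply(recs, function(r) {
    header <- attr(r, "Annot")
    header <- sub("^>", "", header)
    toks <- strsplit(trimws(header), "[[:space:]]+")[[1L]]
    name <- toks[1L]
    offset <- 1L
    offtok <- grep("^offset=", toks, value = TRUE)
    if (length(offtok) > 0L) {
      offset <- suppressWarnings(as.integer(sub("^offset=", "", offtok[1L])))
      if (is.na(offset)) stop("malformed offset token in header: ", header)
    }
    residue_seq(toupper(as.character(r)), offset = offset, name = name)
  })
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}

#' Read reference PreSMo annotations from TSV
#'
#' Expected columns: \code{name}, \code{start}, \code{end}, optional
#' \code{source} (\code{NMR} or \code{X-ray-MoRF}). Intervals are closed and
#' in construct numbering.
#'
#' @param path TSV file with a header line.
#' @param seq optional \code{residue_seq}; if given, annotations are validated
#'   against the construct bounds.
#' @return data.frame of class \code{presmo_annotation}.
#' @export
read_annotations <- function(path, seq = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!"source" %in% names(df)) df$source <- "NMR"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start > df$end)
  if (length(bad) > 0L) {
    stop("malformed annotation at line ", bad[1L] + 1L)
  }
  if (!is.null(seq)) {
    lo <- seq$offset
    hi <- seq$offset + length(seq$aa) - 1L
    out_of_range <- which(df$start < lo | df$end > hi)
    if (length(out_of_range) > 0L) {
      stop(sprintf("annotation %d-%d outside construct bounds %d-%d",
                   df$start[out_of_range[1L]], df$end[out_of_range[1L]],
                   lo, hi))
    }
  }
  class(df) <- c("presmo_annotation", "data.frame")
  df
}
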