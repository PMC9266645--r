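# Anchored, z-score-normalised average signal profiles around site midpoints.

#' Anchored average signal profile (metaprofile)
#'
#' Each anchor contributes a window centred on its midpoint; the per-bin
#' value is the length-weighted mean of the piecewise-constant track over the
#' bin (uncovered bases = 0), averaged across anchors.  Anchors whose window
#' would cross a sequence boundary are excluded (not zero-padded) and counted
#' in `n_dropped`.  Under z-score normalisation the profile is standardised
#' by its own mean and standard deviation over the plotted bins only; a
#' zero-variance profile is returned as all zeros with `degenerate = TRUE`.
#'
#' @param track signal-track `GRanges` with seqlengths set.
#' @param anchors non-empty site-set `GRanges` (midpoints are the centres).
#' @param span half-window in bp (default 1500, i.e. +/-1.5 kb).
#' @param bin bin width in bp (default 10; `span` must be a multiple).
#' @param normalization `"zscore"` or `"raw"`.
#' @return object of class `Profile`: list with `offsets` (bin centres, bp
#'   from anchor), `values`, `n_anchors`, `n_dropped`, `normalization`,
#'   `bin_bp`, `span_bp`, `degenerate`.
#' @export
anchored_profile <- function(track, anchors, span = 1500L, bin = 10L,
                             normalization = c("zscore", "raw")) {
  normalization <- match.arg(normalization)
  if (span %% bin != 0) stop("span must be a multiple of bin")
  if (!length(anchors)) stop("anchor set is empty")
  sl <- GenomeInfoDb::seqlengths(track)
  if (any(is.na(sl))) stop("anchored_profile needs seqlengths on the track")
  nb <- 2L * span %/% bin
  cov <- coverage(track, weight = "score")
  mid <- start(anchors) + (width(anchors) - 1L) %/% 2L
  sq <- as.character(seqnames(anchors))
  win_start <- mid - span
  win_end <- mid + span - 1L
  inb <- win_start >= 1L & win_end <= sl[sq] & sq %in% names(cov)
  n_dropped <- sum(!inb)
  acc <- numeric(nb)
  n_used <- 0L
  for (chr in unique(sq[inb])) {
    i <- which(inb & sq == chr)
    v <- as.numeric(cov[[chr]])
    idx <- outer(win_start[i], 0:(2L * span - 1L), `+`)   # anchors x positions
    m <- matrix(v[t(idx)], nrow = 2L * span)              # positions x anchors
    bs <- matrix(rowsum(m, rep(seq_len(nb), each = bin)), nrow = nb) / bin
    acc <- acc + rowSums(bs)
    n_used <- n_used + length(i)
  }
  if (n_used == 0L) stop("all anchor windows fall outside the sequences")
  vals <- acc / n_used
  degenerate <- FALSE
  if (normalization == "zscore") {
    s <- stats::sd(vals)
    if (s == 0) {
      vals <- rep(0, nb)
      degenerate <- TRUE
    } else {
      vals <- (vals - mean(vals)) / s
    }
  }
  structure(list(offsets = seq(-span + bin / 2, span - bin / 2, by = bin),
                 values = vals, n_anchors = n_used, n_dropped = n_dropped,
                 normalization = normalization, bin_bp = bin, span_bp = span,
                 degenerate = degenerate),
            class = "Profile")
}

#' @export
print.Profile <- function(x, ...) {
  cat(sprintf("Profile: %d bins of %d bp (+/-%d bp), %d anchors (%d dropped), %s%s\n",
              length(x$values), x$bin_bp, x$span_bp, x$n_anchors, x$n_dropped,
              x$normalization, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Locate a profile extremum
#'
#' Returns the offset of the minimal (or maximal) profile value within a
#' region; when several bins attain the extremum (common for sparse count
#' profiles with zero-count bins) the mean offset of the tied bins is
#' returned, which is symmetric and deterministic.
#'
#' @param profile a `Profile`.
#' @param what `"min"` or `"max"`.
#' @param region optional numeric length-2 offset window to search in.
#' @return offset in bp (a bin centre, or the mean of tied bin centres).
#' @export
profile_extremum <- function(profile, what = c("min", "max"), region = NULL) {
  what <- match.arg(what)
  off <- profile$offsets
  v <- profile$values
  if (!is.null(region)) {
    keep <- off >= region[1] & off <= region[2]
    off <- off[keep]; v <- v[keep]
  }
  if (!length(v)) stop("empty search region")
  target <- if (what == "min") min(v) else max(v)
  mean(off[v == target])
}

#' Write a profile as TSV
#'
#' @param profile a `Profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  hdr <- sprintf("# n_anchors=%d n_dropped=%d normalization=%s bin_bp=%d span_bp=%d",
                 profile$n_anchors, profile$n_dropped, profile$normalization,
                 profile$bin_bp, profile$span_bp)
  writeLines(c(hdr, "offset\tvalue",
               sprintf("%g\t%.10g", profile$offsets, profile$values)), path)
  invisible(path)
}
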