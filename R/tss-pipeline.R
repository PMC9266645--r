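# TSS list preparation from CAGE, bidirectional promoter classification,
# and DSB count profiles around TSS anchors.

#' Build a TSS record table
#'
#' @param tss_id,gene_id,seqnames,position,strand,cage vectors of equal
#'   length; `position` is the 1-based TSS base, `strand` "+" or "-",
#'   `cage` the non-negative CAGE expression value.
#' @return data.frame of TSS records.
#' @export
tss_records <- function(tss_id, gene_id, seqnames, position, strand, cage = 0) {
  if (any(!strand %in% c("+", "-"))) stop("TSS strand must be '+' or '-'")
  data.frame(tss_id = as.character(tss_id), gene_id = as.character(gene_id),
             seqnames = as.character(seqnames), position = as.integer(position),
             strand = as.character(strand), cage = as.numeric(cage))
}

#' Prepare a TSS list: deduplicate, drop silent and minor TSSs
#'
#' Exact duplicate records are removed; TSSs with CAGE expression at or below
#' `epsilon` (default 0: "not expressed") are removed; within each gene,
#' TSSs with expression strictly below `minor_frac` of that gene's strongest
#' TSS are removed.  The operation is idempotent.
#'
#' @param tss TSS record data.frame (see [tss_records()]).
#' @param cage optional named vector (by `tss_id`) overriding the `cage`
#'   column; ids missing from it are treated as silent, with a warning.
#' @param minor_frac minor-TSS threshold (default 0.05 = 5% of the major TSS).
#' @param epsilon expression floor defining "silent" (default 0).
#' @return filtered TSS record data.frame.
#' @export
prepare_tss_list <- function(tss, cage = NULL, minor_frac = 0.05, epsilon = 0) {
  if (!is.null(cage)) {
    hit <- match(tss$tss_id, names(cage))
    if (any(is.na(hit)))
      warning(sum(is.na(hit)), " TSS(s) missing from the CAGE table; treated as silent")
    tss$cage <- ifelse(is.na(hit), 0, as.numeric(cage[hit]))
  }
  tss <- tss[!duplicated(tss[c("gene_id", "seqnames", "position", "strand")]), ,
             drop = FALSE]
  tss <- tss[tss$cage > epsilon, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(tss)), tss$gene_id), function(i) {
    i[tss$cage[i] >= minor_frac * max(tss$cage[i])]
  }), use.names = FALSE)
  tss[sort(keep), , drop = FALSE]
}

#' Classify promoters as bidirectional (divergent) or unidirectional
#'
#' A minus/plus TSS pair is bidirectional iff the two TSSs are on the same
#' sequence and opposite strands, their distance is strictly below
#' `max_dist`, and the minus-strand TSS lies at or left of the plus-strand
#' TSS (divergent orientation, so the transcribed regions do not intersect).
#' When a TSS qualifies for several pairs it is paired with its nearest
#' partner (distance ties broken by lower coordinate); the remaining
#' candidates stay unidirectional.  No TSS appears in both outputs.
#'
#' @param tss prepared TSS record data.frame.
#' @param max_dist maximal TSS distance in bp (default 1000, strict).
#' @return object of class `PromoterClass`: list with `bidirectional`
#'   (data.frame `minus_tss_id`, `plus_tss_id`, `seqnames`, `minus_pos`,
#'   `plus_pos`, `distance`) and `unidirectional` (TSS records).
#' @export
classify_promoter_directionality <- function(tss, max_dist = 1000L) {
  minus <- tss[tss$strand == "-", , drop = FALSE]
  plus <- tss[tss$strand == "+", , drop = FALSE]
  cand <- NULL
  if (nrow(minus) && nrow(plus)) {
    mg <- GRanges(minus$seqnames, IRanges(minus$position, width = 1L))
    # window left of each plus TSS in which a divergent minus TSS may sit
    pw <- GRanges(plus$seqnames,
                  IRanges(pmax(1L, plus$position - (max_dist - 1L)),
                          plus$position))
    h <- suppressWarnings(findOverlaps(mg, pw))
    if (length(h)) {
      mi <- queryHits(h); pi <- subjectHits(h)
      d <- plus$position[pi] - minus$position[mi]
      ok <- d >= 0 & d < max_dist
      cand <- data.frame(mi = mi[ok], pi = pi[ok], distance = d[ok])
    }
  }
  pairs <- data.frame(minus_tss_id = character(), plus_tss_id = character(),
                      seqnames = character(), minus_pos = integer(),
                      plus_pos = integer(), distance = integer())
  used_m <- logical(nrow(minus)); used_p <- logical(nrow(plus))
  if (!is.null(cand) && nrow(cand)) {
    ord <- order(cand$distance,
                 pmin(minus$position[cand$mi], plus$position[cand$pi]))
    for (j in ord) {
      mi <- cand$mi[j]; pi <- cand$pi[j]
      if (used_m[mi] || used_p[pi]) next
      used_m[mi] <- used_p[pi] <- TRUE
      pairs <- rbind(pairs, data.frame(
        minus_tss_id = minus$tss_id[mi], plus_tss_id = plus$tss_id[pi],
        seqnames = minus$seqnames[mi], minus_pos = minus$position[mi],
        plus_pos = plus$position[pi], distance = cand$distance[j]))
    }
  }
  uni <- rbind(minus[!used_m, , drop = FALSE], plus[!used_p, , drop = FALSE])
  uni <- uni[order(uni$seqnames, uni$position), , drop = FALSE]
  rownames(uni) <- NULL
  structure(list(bidirectional = pairs, unidirectional = uni,
                 max_dist = max_dist),
            class = "PromoterClass")
}

#' @export
print.PromoterClass <- function(x, ...) {
  cat("PromoterClass:", nrow(x$bidirectional), "bidirectional pairs,",
      nrow(x$unidirectional), "unidirectional TSSs (max_dist",
      x$max_dist, "bp)\n")
  invisible(x)
}

#' Site-count profile around TSS anchors
#'
#' Mean site read count per offset bin across TSS anchors; minus-strand
#' anchors are coordinate-reversed when `strand_aware`, so upstream of the
#' TSS is always on the left.  Offsets are site midpoint minus TSS position;
#' bin b covers offsets `[-span + (b-1)*bin, -span + b*bin)`.
#'
#' @param sites site-set `GRanges`.
#' @param tss TSS record data.frame.
#' @param span half-window in bp (default 1000).
#' @param bin bin width in bp (default 10; `span` must be a multiple).
#' @param strand_aware reverse minus-strand anchors (default TRUE).
#' @return object of class `Profile` (see [anchored_profile()]) with raw
#'   per-bin mean counts.
#' @export
tss_signal_profile <- function(sites, tss, span = 1000L, bin = 10L,
                               strand_aware = TRUE) {
  if (span %% bin != 0) stop("span must be a multiple of bin")
  if (!nrow(tss)) stop("empty anchor list")
  nb <- 2L * span %/% bin
  anchors <- GRanges(tss$seqnames,
                     IRanges(pmax(1L, tss$position - span),
                             tss$position + span - 1L))
  mid <- start(sites) + (width(sites) - 1L) %/% 2L
  midg <- GRanges(seqnames(sites), IRanges(mid, width = 1L))
  h <- findOverlaps(midg, anchors)
  vals <- numeric(nb)
  if (length(h)) {
    off <- mid[queryHits(h)] - tss$position[subjectHits(h)]
    if (strand_aware) {
      flip <- tss$strand[subjectHits(h)] == "-"
      off[flip] <- -off[flip]
    }
    ok <- off >= -span & off < span
    bidx <- (off[ok] + span) %/% bin + 1L
    agg <- tapply(sites$count[queryHits(h)][ok], bidx, sum)
    vals[as.integer(names(agg))] <- agg
  }
  structure(list(offsets = seq(-span + bin / 2, span - bin / 2, by = bin),
                 values = vals / nrow(tss), n_anchors = nrow(tss),
                 n_dropped = 0L, normalization = "raw", bin_bp = bin,
                 span_bp = span, degenerate = FALSE),
            class = "Profile")
}
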