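# From raw per-replicate site data to analysis-ready DSB/4C site sets:
# adapter gating, repeat filtering, replicate intersection, hot-spot and
# quartile subsets, normalised mean coverage.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file (uncompressed or gzipped).
#' @return data.frame with `id`, `sequence`, `quality` (Phred+33 characters).
#' @export
read_fastq <- function(path) {
  rs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(rs),
             sequence = as.character(rs),
             quality = as.character(Biostrings::quality(rs)),
             row.names = NULL)
}

#' Gate reads on a mandatory adapter and quality-trim the insert
#'
#' The DSB library chemistry ligates a fixed adapter at the break point, so a
#' read without the adapter cannot come from a break and is discarded
#' (the `--discard-untrimmed` logic of adapter trimmers).  For surviving
#' reads the adapter and everything 5' of it are removed; the remaining
#' insert is 3'-quality-trimmed (trailing bases below `min_quality`) and kept
#' only if at least `min_len` bases remain.
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param mandatory_adapter adapter nucleotide string (exact match).
#' @param min_len minimal surviving insert length (default 20).
#' @param min_quality Phred threshold for 3' trimming (default 26).
#' @return filtered and trimmed read data.frame.
#' @export
filter_reads_by_adapter <- function(reads, mandatory_adapter,
                                    min_len = 20L, min_quality = 26L) {
  if (!nzchar(mandatory_adapter)) stop("adapter must be non-empty")
  pos <- regexpr(mandatory_adapter, reads$sequence, fixed = TRUE)
  keep <- pos > 0L
  reads <- reads[keep, , drop = FALSE]
  pos <- pos[keep]
  from <- pos + nchar(mandatory_adapter)
  reads$sequence <- substring(reads$sequence, from)
  reads$quality <- substring(reads$quality, from)
  q <- lapply(reads$quality, function(s) utf8ToInt(s) - 33L)
  newlen <- vapply(q, function(v) {
    n <- length(v)
    while (n > 0L && v[n] < min_quality) n <- n - 1L
    n
  }, integer(1))
  reads$sequence <- substr(reads$sequence, 1L, newlen)
  reads$quality <- substr(reads$quality, 1L, newlen)
  reads[nchar(reads$sequence) >= min_len, , drop = FALSE]
}

#' Intersect two site-set replicates
#'
#' Returns the genomic segments present in both replicates, with the
#' per-segment count being the minimum of the two replicate counts
#' (conservative "supported by both replicates" semantics).
#'
#' @param rep1,rep2 site-set `GRanges` on the same genome.
#' @return site-set `GRanges` of intersected segments.
#' @export
intersect_replicates <- function(rep1, rep2) {
  if (!identical(sort(GenomeInfoDb::seqlevels(rep1)),
                 sort(GenomeInfoDb::seqlevels(rep2))))
    stop("replicates are on different genomes")
  c1 <- coverage(rep1, weight = "count")
  c2 <- coverage(rep2, weight = "count")
  m <- methods::as(mapply(function(a, b) pmin(a, b), c1, c2[names(c1)],
                          SIMPLIFY = FALSE), "SimpleRleList")
  gr <- methods::as(m, "GRanges")
  gr <- gr[gr$score > 0]
  gr$count <- as.integer(gr$score)
  gr$score <- NULL
  seqinfo(gr) <- seqinfo(rep1)
  sort(gr, ignore.strand = TRUE)
}

#' Remove sites fully contained in repeat regions
#'
#' Drops every site whose span lies entirely within the union of repeat
#' intervals; partial overlaps are retained.
#'
#' @param sites,repeats site-set `GRanges`.
#' @return the filtered site set.
#' @export
remove_repeat_contained <- function(sites, repeats) {
  overlap_query(sites, repeats, min_frac_a = 1, invert = TRUE)
}

#' Aggregate site counts into fixed-width genomic tiles
#'
#' The genome is tiled into consecutive non-overlapping windows from the
#' start of each sequence; each site contributes its count to the tile
#' containing its midpoint.  Tiles with zero count are omitted.
#'
#' @param sites site-set `GRanges` with bound genome (seqlengths set).
#' @param window_bp tile width in bp (default 1000).
#' @return site-set `GRanges` of tiles with aggregated `count`.
#' @export
tile_counts <- function(sites, window_bp = 1000L) {
  if (window_bp < 1) stop("window_bp must be >= 1")
  sl <- GenomeInfoDb::seqlengths(sites)
  if (any(is.na(sl))) stop("tile_counts needs seqlengths on the site set")
  tiles <- unlist(GenomicRanges::tileGenome(sl, tilewidth = window_bp))
  mid <- GRanges(seqnames(sites),
                 IRanges(start(sites) + (width(sites) - 1L) %/% 2L, width = 1L),
                 seqinfo = seqinfo(sites))
  hits <- findOverlaps(mid, tiles)
  cnt <- integer(length(tiles))
  if (length(hits)) {
    agg <- tapply(sites$count[queryHits(hits)], subjectHits(hits), sum)
    cnt[as.integer(names(agg))] <- agg
  }
  tiles$count <- cnt
  tiles[tiles$count > 0L]
}

#' Select the top fraction of a ranked site set (hot-spot calling)
#'
#' Items with positive count are ranked by descending count; the top
#' `ceil(frac * n_nonzero)` are retained, and every item tied with the cutoff
#' count is retained as well, so the selection is deterministic and
#' order-independent.
#'
#' @param ranked site-set `GRanges` (typically 1-kb tiles from
#'   [tile_counts()], or per-site counts).
#' @param frac fraction to keep, in (0, 1]; default 0.025 (top 2.5%).
#' @param window_bp annotation only: the tiling width that produced `ranked`.
#' @return object of class `HotspotSet`: list with `tiles` (the retained
#'   intervals), `cutoff_count`, `window_bp`, `top_frac`.
#' @export
select_top_fraction <- function(ranked, frac = 0.025, window_bp = NA_integer_) {
  if (!is.numeric(frac) || frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  nz <- ranked[ranked$count > 0L]
  n <- length(nz)
  if (n == 0L)
    return(structure(list(tiles = nz, cutoff_count = NA_integer_,
                          window_bp = window_bp, top_frac = frac),
                     class = "HotspotSet"))
  k <- ceiling(frac * n)
  cutoff <- sort(nz$count, decreasing = TRUE)[k]
  structure(list(tiles = nz[nz$count >= cutoff], cutoff_count = cutoff,
                 window_bp = window_bp, top_frac = frac),
            class = "HotspotSet")
}

#' @export
print.HotspotSet <- function(x, ...) {
  cat("HotspotSet:", length(x$tiles), "windows at top", 100 * x$top_frac,
      "% (count cutoff ", x$cutoff_count, ")\n", sep = " ")
  invisible(x)
}

#' Stratify sites into count quartiles
#'
#' Sites are ranked by descending count; quartile boundaries sit at ranks
#' n/4, n/2 and 3n/4, and ties at a boundary are promoted into the higher
#' (more frequently broken) quartile, so Q1 always contains the top-ranked
#' sites and the four subsets partition the input.
#'
#' @param sites non-empty site-set `GRanges`.
#' @return list of class `QuartileSubsets` with elements `Q1`..`Q4`.
#' @export
stratify_quartiles <- function(sites) {
  n <- length(sites)
  if (n == 0L) stop("cannot stratify an empty site set")
  cnt <- sites$count
  cs <- sort(cnt, decreasing = TRUE)
  b <- ceiling(n * c(1, 2, 3) / 4)
  thr <- cs[b]   # tie promotion: >= threshold joins the higher quartile
  q <- ifelse(cnt >= thr[1], 1L, ifelse(cnt >= thr[2], 2L,
       ifelse(cnt >= thr[3], 3L, 4L)))
  structure(list(Q1 = sites[q == 1L], Q2 = sites[q == 2L],
                 Q3 = sites[q == 3L], Q4 = sites[q == 4L]),
            class = "QuartileSubsets")
}

#' @export
print.QuartileSubsets <- function(x, ...) {
  cat("QuartileSubsets:", paste(sprintf("|%s|=%d", names(x),
                                        vapply(x, length, 0L)), collapse = " "), "\n")
  invisible(x)
}

rpkm_track <- function(rep, normalization) {
  total <- sum(rep$count)
  if (normalization == "rpkm" && total == 0) stop("zero total count in replicate")
  val <- if (normalization == "rpkm")
    rep$count / ((width(rep) / 1000) * (total / 1e6)) else as.numeric(rep$count)
  coverage(rep, weight = val)
}

#' Normalised mean coverage over replicates
#'
#' Per replicate, each interval gets the value `count / (length_kb *
#' total_count / 1e6)` (RPKM) or its raw count; the output is the arithmetic
#' mean of the per-base replicate profiles on the common segment partition.
#'
#' @param replicates list of site-set `GRanges` on the same genome.
#' @param normalization `"rpkm"` or `"none"`.
#' @return signal-track `GRanges` (zero-valued segments omitted).
#' @export
normalized_mean_coverage <- function(replicates, normalization = c("rpkm", "none")) {
  normalization <- match.arg(normalization)
  if (!length(replicates)) stop("need at least one replicate")
  covs <- lapply(replicates, rpkm_track, normalization = normalization)
  mean_cov <- Reduce(`+`, covs) / length(covs)
  gr <- methods::as(mean_cov, "GRanges")
  gr <- gr[gr$score != 0]
  seqinfo(gr) <- seqinfo(replicates[[1]])
  sort(gr, ignore.strand = TRUE)
}

#' Correlation between two signal tracks
#'
#' Both tracks are reduced to `bin_bp` binned means (uncovered bases count as
#' 0) and Pearson's r and Spearman's rho are computed over all bins.
#'
#' @param t1,t2 signal-track `GRanges` with seqlengths set.
#' @param bin_bp bin width in bp.
#' @return named numeric vector `c(pearson_r = , spearman_rho = )`; `NA` with
#'   a warning if either binned track has zero variance.
#' @export
replicate_correlation <- function(t1, t2, bin_bp = 1000L) {
  if (bin_bp < 1) stop("bin_bp must be >= 1")
  sl <- GenomeInfoDb::seqlengths(t1)
  if (any(is.na(sl))) stop("replicate_correlation needs seqlengths")
  bins <- unlist(GenomicRanges::tileGenome(sl, tilewidth = bin_bp))
  v1 <- GenomicRanges::binnedAverage(bins, coverage(t1, weight = "score"), "m")$m
  v2 <- GenomicRanges::binnedAverage(bins, coverage(t2, weight = "score"), "m")$m
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("zero-variance track: correlation undefined")
    return(c(pearson_r = NA_real_, spearman_rho = NA_real_))
  }
  c(pearson_r = stats::cor(v1, v2),
    spearman_rho = stats::cor(v1, v2, method = "spearman"))
}
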