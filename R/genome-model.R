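# Core data model: counted site sets, signal tracks, gene annotation,
# standard-format I/O and the interval overlap engine.

#' Sequence lengths for a (mini-)genome
#'
#' @param lengths named numeric vector, one entry per sequence; all > 0.
#' @return named integer vector with class checks applied.
#' @export
seq_lengths <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("sequence lengths must be a named vector")
  if (any(lengths <= 0)) stop("sequence lengths must be > 0")
  stats::setNames(as.integer(lengths), names(lengths))
}

as_seqinfo <- function(genome) {
  if (methods::is(genome, "Seqinfo")) return(genome)
  genome <- seq_lengths(genome)
  GenomeInfoDb::Seqinfo(seqnames = names(genome), seqlengths = genome)
}

#' Construct a counted site set
#'
#' A site set is a `GRanges` whose `count` metadata column carries the number
#' of reads (DSB events, 4C contacts, ...) supporting each interval.  Sites
#' are unstranded by default (DSBs have no strand); strand is kept if present.
#'
#' @param gr a `GRanges` (or anything coercible) with an optional `count`
#'   metadata column (default 1 per interval).
#' @param genome named vector of sequence lengths or a `Seqinfo`; optional,
#'   but required to bind sites to a genome (out-of-bounds intervals and
#'   unknown sequence names then become errors).
#' @param label free-text label stored in `metadata(x)$label`.
#' @return a sorted `GRanges` with integer `count`.
#' @export
site_set <- function(gr, genome = NULL, label = NULL) {
  gr <- methods::as(gr, "GRanges")
  if (is.null(gr$count)) gr$count <- rep(1L, length(gr))
  gr$count <- as.integer(gr$count)
  if (any(is.na(gr$count)) || any(gr$count < 0))
    stop("site counts must be non-negative integers")
  if (!is.null(genome)) {
    si <- as_seqinfo(genome)
    bad <- setdiff(as.character(unique(seqnames(gr))), GenomeInfoDb::seqnames(si))
    if (length(bad))
      stop("sites reference sequences absent from the genome: ",
           paste(bad, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(si)
    suppressWarnings(seqinfo(gr) <- si)   # out-of-bounds raise an error below
    sl <- GenomeInfoDb::seqlengths(si)[as.character(seqnames(gr))]
    if (any(start(gr) < 1L) || any(end(gr) > sl))
      stop("interval exceeds its sequence length")
  }
  gr <- sort(gr, ignore.strand = TRUE)
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' Construct a piecewise-constant signal track
#'
#' bedGraph semantics: sorted, non-overlapping segments with a finite numeric
#' `score`; bases not covered by a segment have value 0.
#'
#' @param gr `GRanges` with a numeric `score` column.
#' @param genome optional sequence lengths / `Seqinfo`.
#' @return a sorted `GRanges` with `score`.
#' @export
signal_track <- function(gr, genome = NULL) {
  gr <- methods::as(gr, "GRanges")
  if (is.null(gr$score)) stop("a signal track needs a numeric 'score' column")
  gr$score <- as.numeric(gr$score)
  if (any(!is.finite(gr$score))) stop("signal values must be finite")
  if (!is.null(genome)) seqinfo(gr) <- as_seqinfo(genome)
  gr <- sort(gr, ignore.strand = TRUE)
  cov_ok <- all(vapply(split(ranges(gr), as.character(seqnames(gr))),
                       function(r) sum(width(IRanges::reduce(r, min.gapwidth = 0L))) ==
                         sum(width(r)),
                       logical(1)))
  if (!cov_ok) stop("signal track segments must not overlap")
  gr
}

validate_lines <- function(path, min_fields, numeric_fields) {
  ln <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", ln) & nzchar(trimws(ln))
  for (i in which(keep)) {
    f <- strsplit(trimws(ln[i]), "[ \t]+")[[1]]
    if (length(f) < min_fields)
      stop(sprintf("malformed line %d in '%s': expected >= %d fields, found %d",
                   i, path, min_fields, length(f)))
    for (j in numeric_fields[numeric_fields <= length(f)])
      if (is.na(suppressWarnings(as.numeric(f[j]))))
        stop(sprintf("malformed line %d in '%s': field %d is not numeric", i, path, j))
  }
  invisible(sum(keep))
}

#' Read intervals or a signal track from a standard format
#'
#' BED is parsed as 0-based half-open and converted to the internal 1-based
#' closed representation; GFF/GTF is 1-based closed already; bedGraph column 4
#' becomes the track value.  For BED the score column becomes the site
#' `count` (absent columns default to count 1, strand `*`).
#'
#' @param path input file.
#' @param format one of `"bed"`, `"bedgraph"`, `"gtf"`, `"gff3"`.
#' @param genome optional sequence lengths; unknown sequence names error out.
#' @return a site-set `GRanges` (BED/GTF) or signal-track `GRanges` (bedGraph).
#' @export
read_intervals <- function(path, format = c("bed", "bedgraph", "gtf", "gff3"),
                           genome = NULL) {
  format <- match.arg(tolower(format), c("bed", "bedgraph", "gtf", "gff3"))
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
    bed      = validate_lines(path, 3L, c(2L, 3L)),
    bedgraph = validate_lines(path, 4L, c(2L, 3L, 4L)),
    gtf      = validate_lines(path, 8L, c(4L, 5L)),
    gff3     = validate_lines(path, 8L, c(4L, 5L)))
  gr <- rtracklayer::import(path, format = if (format == "bedgraph") "bedGraph" else format)
  if (format == "bedgraph") return(signal_track(gr, genome))
  if (format == "bed") {
    cnt <- if (!is.null(gr$score)) as.integer(gr$score) else rep(1L, length(gr))
    cnt[is.na(cnt)] <- 1L
    mcols(gr)$count <- cnt
    gr$score <- NULL
  } else {
    gr$count <- rep(1L, length(gr))
  }
  site_set(gr, genome)
}

merge_equal_segments <- function(track) {
  if (length(track) < 2L) return(track)
  o <- order(as.factor(seqnames(track)), start(track))
  track <- track[o]
  same <- as.character(seqnames(track))[-1] == as.character(seqnames(track))[-length(track)] &
    start(track)[-1] == end(track)[-length(track)] + 1L &
    track$score[-1] == track$score[-length(track)]
  grp <- cumsum(c(TRUE, !same))
  if (all(same == FALSE)) return(track)
  s <- tapply(start(track), grp, min)
  e <- tapply(end(track), grp, max)
  first <- !duplicated(grp)
  GRanges(seqnames(track)[first], IRanges(as.integer(s), as.integer(e)),
          score = track$score[first], seqinfo = seqinfo(track))
}

#' Write intervals or a signal track
#'
#' Site sets are written as BED (count in the score column, 0-based half-open
#' on disk); signal tracks as bedGraph, with adjacent equal-value segments
#' merged.  `read_intervals(write_intervals(x))` round-trips coordinates,
#' counts/values and strand.
#'
#' @param x site-set or signal-track `GRanges`.
#' @param path output file.
#' @param format `"bed"` or `"bedgraph"` (default guessed from the presence of
#'   a `score`/`count` column).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = NULL) {
  if (is.null(format))
    format <- if (!is.null(x$score) && is.null(x$count)) "bedgraph" else "bed"
  format <- match.arg(tolower(format), c("bed", "bedgraph"))
  if (format == "bedgraph") {
    x <- merge_equal_segments(x)
    rtracklayer::export(x, path, format = "bedGraph")
  } else {
    y <- x
    y$score <- as.numeric(y$count)
    y$count <- NULL
    if (is.null(y$name))
      y$name <- sprintf("site%06d", seq_along(y))
    rtracklayer::export(y, path, format = "bed")
  }
  invisible(path)
}

#' Fraction-of-overlap interval query
#'
#' Returns the intervals of `a` for which at least `min_frac_a` of their
#' length is covered by the union of intervals of `b` (the semantics of
#' `bedtools intersect -f`); with `invert = TRUE`, the complement subset of
#' `a`.  `min_frac_a = 1` with `invert = TRUE` reproduces the "-v -f 1.0"
#' removal of intervals fully contained in a region set.
#'
#' @param a,b site-set `GRanges` on the same genome.
#' @param min_frac_a required covered fraction of each `a` interval, in (0, 1].
#' @param invert return the non-qualifying intervals instead.
#' @return subset of `a`, original order preserved.
#' @export
overlap_query <- function(a, b, min_frac_a = 1, invert = FALSE) {
  if (!is.numeric(min_frac_a) || length(min_frac_a) != 1L ||
      min_frac_a <= 0 || min_frac_a > 1)
    stop("min_frac_a must be a single value in (0, 1]")
  br <- IRanges::reduce(granges(b), ignore.strand = TRUE)
  hits <- findOverlaps(a, br, ignore.strand = TRUE)
  ov <- width(pintersect(granges(a)[queryHits(hits)], br[subjectHits(hits)]))
  covered <- rep(0, length(a))
  if (length(hits)) {
    agg <- tapply(ov, queryHits(hits), sum)
    covered[as.integer(names(agg))] <- agg
  }
  keep <- covered >= min_frac_a * width(a)
  if (invert) a[!keep] else a[keep]
}

#' Gene annotation container
#'
#' Bundles gene spans and their exons; [project_annotation()] derives the
#' intron, UTR, promoter and TSS features used downstream.
#'
#' @param genes `GRanges` with mandatory `gene_id` (unique) and optional
#'   `name`, `utr5_len`, `utr3_len` metadata columns; strand must be + or -.
#' @param exons `GRangesList` named by `gene_id`, one entry per gene.
#' @param genome sequence lengths or `Seqinfo`.
#' @return object of class `GeneAnnotation`.
#' @export
gene_annotation <- function(genes, exons, genome = NULL) {
  if (is.null(genes$gene_id) || anyDuplicated(genes$gene_id))
    stop("genes need a unique 'gene_id' column")
  if (any(strand(genes) == "*")) stop("genes must be stranded")
  if (is.null(genes$name)) genes$name <- genes$gene_id
  if (!is.null(genome)) {
    si <- as_seqinfo(genome)
    seqinfo(genes) <- si
  }
  exons <- methods::as(exons[genes$gene_id], "CompressedGRangesList")
  gspan <- ranges(genes)
  for (i in seq_along(genes)) {
    ex <- ranges(exons[[i]])
    if (length(ex) == 0L) stop("gene ", genes$gene_id[i], " has no exons")
    if (min(start(ex)) < start(gspan)[i] || max(end(ex)) > end(gspan)[i])
      stop("exon outside gene span for gene ", genes$gene_id[i])
  }
  structure(list(genes = genes, exons = exons,
                 genome = if (is.null(genome)) NULL else seq_lengths(
                   stats::setNames(GenomeInfoDb::seqlengths(as_seqinfo(genome)),
                                   GenomeInfoDb::seqnames(as_seqinfo(genome))))),
            class = "GeneAnnotation")
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat("GeneAnnotation:", length(x$genes), "genes on",
      length(unique(as.character(seqnames(x$genes)))), "sequences")
  if (!is.null(x$tss)) cat(" (projected)")
  cat("\n")
  invisible(x)
}

#' Derive introns, UTRs, promoter windows and TSS points
#'
#' TSS is the 5' end of the gene span (strand-aware: rightmost base for minus
#' strand).  The promoter window extends `promoter_window[1]` bp upstream and
#' `promoter_window[2]` bp downstream of the TSS, strand-aware, trimmed to the
#' sequence.  Introns are the gene span minus the exons.  UTR windows are the
#' first `utr5_len` / last `utr3_len` bases of the gene span (strand-aware);
#' genes without these columns get 200/300 bp defaults capped at the terminal
#' exon width.
#'
#' @param ann a `GeneAnnotation`.
#' @param promoter_window numeric length-2, upstream and downstream bp.
#' @return the annotation with `$tss`, `$promoters`, `$introns`, `$utr5`,
#'   `$utr3` added.
#' @export
project_annotation <- function(ann, promoter_window = c(1000, 100)) {
  stopifnot(inherits(ann, "GeneAnnotation"))
  genes <- ann$genes
  tss <- GenomicRanges::promoters(genes, upstream = 0, downstream = 1)
  prom <- GenomicRanges::trim(GenomicRanges::promoters(
    genes, upstream = promoter_window[1], downstream = promoter_window[2]))
  introns <- IRanges::psetdiff(granges(genes), ann$exons[genes$gene_id])
  u5len <- if (!is.null(genes$utr5_len)) genes$utr5_len else rep(200L, length(genes))
  u3len <- if (!is.null(genes$utr3_len)) genes$utr3_len else rep(300L, length(genes))
  first_w <- vapply(seq_along(genes), function(i) {
    ex <- ann$exons[[i]]
    if (as.character(strand(genes)[i]) == "+") width(ex)[1] else width(ex)[length(ex)]
  }, numeric(1))
  last_w <- vapply(seq_along(genes), function(i) {
    ex <- ann$exons[[i]]
    if (as.character(strand(genes)[i]) == "+") width(ex)[length(ex)] else width(ex)[1]
  }, numeric(1))
  u5len <- pmin(as.integer(u5len), as.integer(first_w))
  u3len <- pmin(as.integer(u3len), as.integer(last_w))
  utr5 <- resize(granges(genes), pmax(u5len, 1L), fix = "start")
  utr3 <- resize(granges(genes), pmax(u3len, 1L), fix = "end")
  utr5$gene_id <- utr3$gene_id <- tss$gene_id <- prom$gene_id <- genes$gene_id
  ann$tss <- tss
  ann$promoters <- prom
  ann$introns <- introns
  ann$utr5 <- utr5[u5len > 0L]
  ann$utr3 <- utr3[u3len > 0L]
  ann$promoter_window <- promoter_window
  ann
}

#' Read a gene annotation from GTF/GFF3
#'
#' Uses `gene` and `exon` features; exons are grouped by their `gene_id`
#' attribute.  Missing `gene` rows are reconstructed as the exon extremes.
#'
#' @param path GTF/GFF3 file.
#' @param genome optional sequence lengths.
#' @return a `GeneAnnotation`.
#' @export
read_gene_annotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path)
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  exl <- split(granges(ex), ex$gene_id)
  exl <- methods::as(lapply(exl, function(g) sort(g)), "GRangesList")
  gn <- gr[gr$type == "gene"]
  if (length(gn)) {
    genes <- granges(gn)
    genes$gene_id <- gn$gene_id
    genes$name <- if (!is.null(gn$gene_name)) gn$gene_name else gn$gene_id
  } else {
    rng <- unlist(range(exl))
    genes <- rng
    genes$gene_id <- names(rng)
    st <- vapply(split(as.character(strand(ex)), ex$gene_id), `[`, "", 1)
    strand(genes) <- st[genes$gene_id]
    genes$name <- genes$gene_id
  }
  gene_annotation(genes, exl, genome)
}

#' Write a gene annotation as GTF
#'
#' @param ann a `GeneAnnotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  genes <- granges(ann$genes)
  genes$type <- "gene"
  genes$gene_id <- ann$genes$gene_id
  genes$gene_name <- ann$genes$name
  ex <- unlist(ann$exons)
  exg <- granges(ex)
  exg$type <- "exon"
  exg$gene_id <- rep(names(ann$exons), lengths(ann$exons))
  exg$gene_name <- ann$genes$name[match(exg$gene_id, ann$genes$gene_id)]
  all <- c(genes, exg)
  all$source <- "dsbscape"
  all$transcript_id <- paste0(all$gene_id, ".t1")
  rtracklayer::export(sort(all), path, format = "gtf")
  invisible(path)
}
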