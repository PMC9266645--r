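# Mapping site sets onto genes and genomic categories, ranked target-gene
# lists, and category breakdowns against the genome background.

#' Assign sites to genes
#'
#' A site contributes its read count to every gene whose span it overlaps
#' (a site between two overlapping genes counts toward both); genes with no
#' overlapping site are absent from the table.
#'
#' @param sites site-set `GRanges`.
#' @param ann a `GeneAnnotation`.
#' @return data.frame (`GeneHitTable`) with `gene_id`, `name`, `site_count`
#'   (summed read counts) and `n_sites`, sorted by descending `site_count`.
#' @export
assign_sites_to_genes <- function(sites, ann) {
  stopifnot(inherits(ann, "GeneAnnotation"))
  genes <- ann$genes
  hits <- findOverlaps(sites, genes, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(gene_id = character(), name = character(),
                      site_count = integer(), n_sites = integer()))
  counts <- tapply(sites$count[queryHits(hits)], subjectHits(hits), sum)
  nsites <- tapply(queryHits(hits), subjectHits(hits), length)
  idx <- as.integer(names(counts))
  out <- data.frame(gene_id = genes$gene_id[idx],
                    name = genes$name[idx],
                    site_count = as.integer(counts),
                    n_sites = as.integer(nsites))
  out[order(-out$site_count, out$gene_id), , drop = FALSE]
}

#' Select the most frequently targeted genes
#'
#' Genes are ranked by descending `site_count`.  In `fraction` mode the top
#' `ceil(value * n)` genes of the `n` genes with at least one site are
#' selected; in `count` mode the top `value` genes.  Ties at the cutoff are
#' always included.
#'
#' @param hits a `GeneHitTable` from [assign_sites_to_genes()].
#' @param mode `"fraction"` or `"count"`.
#' @param value fraction in (0, 1] or a positive integer.
#' @return character vector of gene ids.
#' @export
select_top_genes <- function(hits, mode = c("fraction", "count"), value) {
  mode <- match.arg(mode)
  if (value <= 0) stop("value must be positive")
  if (mode == "fraction" && value > 1) stop("fraction must be <= 1")
  n <- nrow(hits)
  if (n == 0L) return(character())
  k <- if (mode == "fraction") ceiling(value * n) else min(as.integer(value), n)
  cnt <- sort(hits$site_count, decreasing = TRUE)
  cutoff <- cnt[k]
  if (all(hits$site_count == cutoff) && n > k)
    warning("all genes tied at the cutoff; returning every hit gene")
  hits$gene_id[hits$site_count >= cutoff]
}

#' Category precedence order used for disjoint genomic accounting
#' @export
CATEGORY_ORDER <- c("TSS", "promoter", "5'UTR", "3'UTR", "exon", "intron",
                    "LINE", "SINE", "LTR", "transposon", "intergenic")

exclusive_category_ranges <- function(ann, repeats_by_class, tss_halfwidth) {
  stopifnot(!is.null(ann$tss))   # must be projected
  sl <- GenomeInfoDb::seqlengths(ann$genes)
  if (any(is.na(sl))) stop("categorize_sites needs seqlengths on the annotation")
  si <- seqinfo(ann$genes)
  norm <- function(g) {
    if (is.null(g) || length(g) == 0L) return(GRanges(seqinfo = si))
    g <- granges(g)
    GenomeInfoDb::seqlevels(g) <- GenomeInfoDb::seqnames(si)
    suppressWarnings(seqinfo(g) <- si)
    IRanges::reduce(GenomicRanges::trim(g), ignore.strand = TRUE)
  }
  tssw <- GenomicRanges::trim(resize(granges(ann$tss), 2L * tss_halfwidth + 1L,
                                     fix = "center"))
  cats <- list(
    "TSS" = tssw,
    "promoter" = ann$promoters,
    "5'UTR" = ann$utr5,
    "3'UTR" = ann$utr3,
    "exon" = unlist(ann$exons),
    "intron" = unlist(ann$introns),
    "LINE" = repeats_by_class[["LINE"]],
    "SINE" = repeats_by_class[["SINE"]],
    "LTR" = repeats_by_class[["LTR"]],
    "transposon" = repeats_by_class[["transposon"]])
  acc <- GRanges(seqinfo = si)
  out <- vector("list", length(cats))
  names(out) <- names(cats)
  for (nm in names(cats)) {
    g <- norm(cats[[nm]])
    excl <- GenomicRanges::setdiff(g, acc, ignore.strand = TRUE)
    out[[nm]] <- excl
    acc <- IRanges::reduce(c(acc, excl), ignore.strand = TRUE)
  }
  out
}

#' Genomic-category breakdown of a site set
#'
#' Each site is assigned exactly one category by its midpoint under the
#' precedence order TSS > promoter > 5'UTR > 3'UTR > exon > intron > LINE >
#' SINE > LTR > transposon > intergenic; the genome background is the bp
#' fraction of each category under the same precedence (every base counted
#' once).  Site and background fractions are compared per category with a
#' two-proportion z-test (pooled), the asymptotic form of a t-test for two
#' independent proportions.
#'
#' @param sites site-set `GRanges`.
#' @param ann a projected `GeneAnnotation` (see [project_annotation()]).
#' @param repeats_by_class named list of `GRanges` with any of the elements
#'   `LINE`, `SINE`, `LTR`, `transposon`; a flat repeat set may be passed as
#'   `list(transposon = repeats)`.
#' @param tss_halfwidth half-width of the TSS window in bp (default 100, i.e.
#'   TSS = point +/- 100 bp).
#' @return data.frame (`CategoryBreakdown`) with `category`, `n_sites`,
#'   `site_frac`, `genome_frac`, `z`, `p_value`; fractions each sum to 1.
#' @export
categorize_sites <- function(sites, ann, repeats_by_class = list(),
                             tss_halfwidth = 100L) {
  excl <- exclusive_category_ranges(ann, repeats_by_class, tss_halfwidth)
  sl <- GenomeInfoDb::seqlengths(ann$genes)
  total_bp <- sum(as.numeric(sl))
  bp <- vapply(excl, function(g) sum(as.numeric(width(g))), numeric(1))
  bp <- c(bp, "intergenic" = total_bp - sum(bp))
  genome_frac <- bp / total_bp

  mid <- GRanges(seqnames(sites),
                 IRanges(start(sites) + (width(sites) - 1L) %/% 2L, width = 1L))
  cat_idx <- rep(length(excl) + 1L, length(sites))   # default: intergenic
  for (i in rev(seq_along(excl))) {                  # apply from lowest precedence up
    if (length(excl[[i]]))
      cat_idx[overlapsAny(mid, excl[[i]], ignore.strand = TRUE)] <- i
  }
  n <- length(sites)
  n_sites <- tabulate(cat_idx, nbins = length(excl) + 1L)
  site_frac <- if (n > 0) n_sites / n else rep(0, length(n_sites))

  # pooled two-proportion z, site fraction vs genome bp fraction
  p_pool <- (n_sites + bp) / (n + total_bp)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n + 1 / total_bp))
  z <- ifelse(se > 0, (site_frac - genome_frac) / se, 0)
  data.frame(category = CATEGORY_ORDER,
             n_sites = n_sites,
             site_frac = site_frac,
             genome_frac = as.numeric(genome_frac),
             z = as.numeric(z),
             p_value = as.numeric(2 * stats::pnorm(-abs(z))))
}
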