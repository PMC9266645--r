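# Seeded generator of a mini-genome and every derived input the analysis
# consumes, with a ledger of planted truths for parameter-recovery tests.

rand_gene_structure <- function(len, n_exons) {
  # exon/intron layout spanning [1, len]: first exon starts at 1, last ends at len
  if (n_exons == 1L) return(IRanges(1L, len))
  n_parts <- 2L * n_exons - 1L
  w <- rgeom(n_parts, 1 / 400) + 100L       # exon/intron widths, mean ~500
  w <- pmax(50L, round(w * len / sum(w)))
  w[n_parts] <- len - sum(w[-n_parts])
  if (w[n_parts] < 50L) {                   # rebalance a degenerate tail
    w <- rep(len %/% n_parts, n_parts)
    w[n_parts] <- len - sum(w[-n_parts])
  }
  s <- cumsum(c(1L, w[-n_parts]))
  IRanges(s[seq(1, n_parts, by = 2)], s[seq(1, n_parts, by = 2)] +
            w[seq(1, n_parts, by = 2)] - 1L)
}

#' Generate a synthetic mini-genome with gene, TSS and repeat structure
#'
#' Genes (1-8 exons, ~50/50 strands) are placed without overlap with
#' inter-gene gaps of at least 1.5 kb, except that a stated fraction of
#' genes is arranged in divergent (bidirectional-promoter) pairs: a
#' minus-strand gene followed by a plus-strand gene with TSS distance
#' uniform in [100, 999] bp.  Repeat intervals (LINE/SINE/LTR/transposon)
#' cover approximately `repeat_frac` of the genome and avoid TSS
#' neighbourhoods.  All planted structure is recorded in the ledger.
#'
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_len chromosome length in bp (default 5e6).
#' @param n_genes total gene count (default 400).
#' @param repeat_frac target repeat bp fraction (default 0.15).
#' @param bidirectional_frac fraction of genes in divergent pairs (default 0.1).
#' @param seed RNG seed.
#' @return list with `ann` (`GeneAnnotation`), `repeats` (site-set `GRanges`
#'   with `class` column), `genome` (named lengths) and `ledger`.
#' @export
make_genome <- function(n_chrom = 2L, chrom_len = 5e6, n_genes = 400L,
                        repeat_frac = 0.15, bidirectional_frac = 0.1,
                        seed = 42L) {
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  genome <- seq_lengths(stats::setNames(rep(chrom_len, n_chrom), chroms))
  per_chrom <- rep(n_genes %/% n_chrom, n_chrom)
  per_chrom[1] <- per_chrom[1] + n_genes %% n_chrom
  n_pairs <- floor(bidirectional_frac * n_genes / 2)

  gene_len <- function() round(runif(1, 2000, 15000))
  need <- n_genes * (15000 + 3000)
  if (need / 2 > chrom_len * n_chrom)
    stop("cannot place ", n_genes, " genes; suggested chrom_len >= ",
         ceiling(need / 2 / n_chrom))

  rows <- list(); exl <- list(); gi <- 0L
  pair_rows <- list()
  pairs_left <- n_pairs
  for (ci in seq_len(n_chrom)) {
    pos <- 1L
    placed <- 0L
    while (placed < per_chrom[ci]) {
      gap <- round(runif(1, 1500, 8000))
      pos <- pos + gap
      two_left <- per_chrom[ci] - placed >= 2L
      as_pair <- pairs_left > 0L && two_left && runif(1) < 0.35
      if (as_pair) {
        l1 <- gene_len(); d <- sample(100:999, 1); l2 <- gene_len()
        if (pos + l1 + d + l2 > chrom_len - 2000) break
        gi <- gi + 1L
        id1 <- sprintf("gene%04d", gi)
        # minus-strand gene: TSS at its right end
        rows[[gi]] <- data.frame(seq = chroms[ci], start = pos,
                                 end = pos + l1 - 1L, strand = "-", id = id1)
        exl[[gi]] <- rand_gene_structure(l1, sample(1:8, 1))
        m_tss <- pos + l1 - 1L
        gi <- gi + 1L
        id2 <- sprintf("gene%04d", gi)
        p_start <- m_tss + d
        rows[[gi]] <- data.frame(seq = chroms[ci], start = p_start,
                                 end = p_start + l2 - 1L, strand = "+", id = id2)
        exl[[gi]] <- rand_gene_structure(l2, sample(1:8, 1))
        pair_rows[[length(pair_rows) + 1L]] <-
          data.frame(minus_gene = id1, plus_gene = id2, seqnames = chroms[ci],
                     minus_pos = m_tss, plus_pos = p_start, distance = d)
        pos <- p_start + l2
        placed <- placed + 2L
        pairs_left <- pairs_left - 1L
      } else {
        l <- gene_len()
        if (pos + l > chrom_len - 2000) break
        gi <- gi + 1L
        rows[[gi]] <- data.frame(seq = chroms[ci], start = pos,
                                 end = pos + l - 1L,
                                 strand = sample(c("+", "-"), 1),
                                 id = sprintf("gene%04d", gi))
        exl[[gi]] <- rand_gene_structure(l, sample(1:8, 1))
        pos <- pos + l
        placed <- placed + 1L
      }
    }
  }
  df <- do.call(rbind, rows)
  genes <- GRanges(df$seq, IRanges(df$start, df$end), strand = df$strand,
                   seqinfo = as_seqinfo(genome))
  genes$gene_id <- df$id
  genes$name <- toupper(df$id)
  genes$utr5_len <- 200L
  genes$utr3_len <- 300L
  names(exl) <- df$id
  exons <- methods::as(lapply(seq_along(exl), function(i)
    GenomicRanges::shift(GRanges(df$seq[i], exl[[i]],
                                 seqinfo = as_seqinfo(genome)),
                         df$start[i] - 1L)),
    "GRangesList")
  names(exons) <- df$id
  ann <- gene_annotation(genes, exons, genome)

  # repeats: avoid +/-1.1 kb around every TSS, stay disjoint from each other
  tss <- GenomicRanges::promoters(genes, 0, 1)
  excl <- IRanges::reduce(resize(granges(tss), 2201L, fix = "center"),
                          ignore.strand = TRUE)
  target_bp <- repeat_frac * sum(as.numeric(genome))
  classes <- c("LINE", "SINE", "LTR", "transposon")
  placed_rep <- GRanges(seqinfo = as_seqinfo(genome))
  got <- 0; rounds <- 0L
  while (got < target_bp && rounds < 200L) {
    rounds <- rounds + 1L
    nb <- 2000L
    chr <- sample(chroms, nb, replace = TRUE)
    w <- round(runif(nb, 300, 3000))
    s <- floor(runif(nb, 1, chrom_len - w))
    cand <- GRanges(chr, IRanges(as.integer(s), width = as.integer(w)),
                    seqinfo = as_seqinfo(genome))
    cand <- cand[!overlapsAny(cand, excl) & !overlapsAny(cand, placed_rep)]
    # drop candidates overlapping an earlier candidate in this batch
    h <- findOverlaps(cand, cand)
    bad <- unique(queryHits(h)[queryHits(h) > subjectHits(h)])
    if (length(bad)) cand <- cand[-bad]
    cw <- cumsum(as.numeric(width(cand)))
    keep <- which(got + cw - as.numeric(width(cand)) < target_bp)
    cand <- cand[keep]
    got <- got + sum(as.numeric(width(cand)))
    placed_rep <- c(placed_rep, cand)
  }
  repeats <- placed_rep
  repeats$class <- sample(classes, length(repeats), replace = TRUE)
  repeats$count <- 1L
  repeats <- sort(repeats, ignore.strand = TRUE)

  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(minus_gene = character(), plus_gene = character(),
               seqnames = character(), minus_pos = integer(),
               plus_pos = integer(), distance = integer())
  ledger <- list(seed = seed,
                 params = list(n_chrom = n_chrom, chrom_len = chrom_len,
                               n_genes = n_genes, repeat_frac = repeat_frac,
                               bidirectional_frac = bidirectional_frac),
                 planted_pairs = pairs,
                 repeat_ranges = granges(repeats),
                 repeat_bp = got)
  list(ann = ann, repeats = repeats, genome = genome, ledger = ledger)
}

laplace_sample <- function(n, location, scale) {
  u <- runif(n) - 0.5
  location - scale * sign(u) * log(1 - 2 * abs(u))
}

#' Generate two noisy DSB site replicates with planted structure
#'
#' A shared latent site map is built from four components: a uniform Poisson
#' background of 1-bp cut sites (geometric read multiplicities); fold-elevated
#' intensity in designated DSB-target gene bodies; TSS-flank enrichment with
#' peaks near +/-300 bp and a central dip (a linear suppression ramp within
#' `tss_dip_halfwidth` of the TSS, zero at the TSS itself); and hot-spot
#' tiles planted at the boundaries of 50-150 kb domains, each carrying
#' `hotspot_fold` times the mean background tile read count.  The two
#' replicates are independent binomial thinnings (per-read retention
#' `1 - noise`) of the latent map.
#'
#' @param ann a `GeneAnnotation`.
#' @param ledger ledger from [make_genome()] (updated and returned).
#' @param background_rate background cut sites per Mb (default 700).
#' @param gene_enrichment intensity fold in target gene bodies (default 20).
#' @param tss_flank_enrichment flank enrichment fold over the local
#'   background in the promoter window (default 70; 0 disables).
#' @param tss_dip_halfwidth half-width of the central protected dip in bp
#'   (default 150).
#' @param hotspot_domain_len length-2 range of hot-spot-delimited domain
#'   lengths in bp (default c(5e4, 1.5e5)).
#' @param hotspot_fold hot-spot tile read count as a multiple of the mean
#'   background tile read count (default 150; 0 disables).
#' @param target_frac fraction of genes designated DSB targets (default 0.1).
#' @param noise per-replicate read dropout fraction in [0, 1) (default 0.15).
#' @param seed RNG seed.
#' @return list with `rep1`, `rep2` (site-set `GRanges`) and the updated
#'   `ledger` (fields `dsb_target_genes`, `hotspot_tiles`, `expressed_tss`).
#' @export
make_dsb_replicates <- function(ann, ledger, background_rate = 700,
                                gene_enrichment = 20, tss_flank_enrichment = 70,
                                tss_dip_halfwidth = 150L,
                                hotspot_domain_len = c(5e4, 1.5e5),
                                hotspot_fold = 150, target_frac = 0.1,
                                noise = 0.15, seed = 42L) {
  if (noise >= 1 || noise < 0) stop("noise (dropout) must be in [0, 1)")
  if (background_rate <= 0) stop("background_rate must be positive")
  set.seed(seed + 1L)
  genome <- ann$genome
  genes <- ann$genes
  chroms <- names(genome)

  pos <- integer(0); chr <- character(0); cnt <- integer(0)
  add <- function(p, ch, k) {
    pos <<- c(pos, as.integer(p)); chr <<- c(chr, ch); cnt <<- c(cnt, as.integer(k))
  }

  # 1. uniform background, single-read cuts with geometric extra multiplicity
  for (cm in chroms) {
    n_bg <- rpois(1, background_rate * genome[[cm]] / 1e6)
    add(sample.int(genome[[cm]], n_bg, replace = TRUE), rep(cm, n_bg),
        1L + rgeom(n_bg, 0.9))   # stochastic one-off cuts: nearly always single-read
  }
  # mean reads per 1-kb background tile: site rate x mean multiplicity of 1+Geom(0.9)
  bg_tile_reads <- background_rate / 1000 * (1 + 0.1 / 0.9)

  # 2. DSB-target gene bodies
  n_target <- round(target_frac * length(genes))
  target_ids <- sort(sample(genes$gene_id, n_target))
  if (gene_enrichment > 1) {
    tg <- genes[genes$gene_id %in% target_ids]
    extra <- rpois(length(tg), (gene_enrichment - 1) * background_rate *
                     width(tg) / 1e6)
    for (i in seq_along(tg)) {
      if (extra[i] == 0) next
      p <- start(tg)[i] + sample.int(width(tg)[i], extra[i], replace = TRUE) - 1L
      add(p, rep(as.character(seqnames(tg)[i]), extra[i]),
          1L + rgeom(extra[i], 0.6))   # recurrent breakage in target bodies
    }
  }

  # 3. TSS flanks with central dip (anchors: TSSs of expressed genes; the
  #    expressed set is fixed here and recorded so the expression generator
  #    can agree with it)
  silent_plan <- ledger$silent_genes
  if (is.null(silent_plan)) {
    protect <- unique(c(target_ids, ledger$planted_pairs$minus_gene,
                        ledger$planted_pairs$plus_gene))
    pool <- setdiff(genes$gene_id, protect)
    n_sil <- min(length(pool), round(0.4 * length(genes)))
    silent_plan <- sort(sample(pool, n_sil))
  }
  expressed <- setdiff(genes$gene_id, silent_plan)
  tss_all <- GenomicRanges::promoters(genes, 0, 1)
  anchors <- tss_all[genes$gene_id %in% expressed]
  if (tss_flank_enrichment > 0 && length(anchors)) {
    # per anchor: Laplace flank peaks at +/-300 bp plus a uniform pedestal
    # over +/-1000 bp, both thinned by the dip ramp min(1, |offset|/halfwidth)
    bg_per_bp <- background_rate / 1e6
    peak_rate <- tss_flank_enrichment * bg_per_bp * 1200 * 0.6
    ped_rate <- tss_flank_enrichment * bg_per_bp * 2000 * 0.4
    for (i in seq_along(anchors)) {
      a <- start(anchors)[i]
      cm <- as.character(seqnames(anchors)[i])
      n_peak <- rpois(1, peak_rate)
      n_ped <- rpois(1, ped_rate)
      off <- c(sample(c(-1, 1), n_peak, replace = TRUE) *
                 pmin(600, pmax(50, laplace_sample(n_peak, 300, 60))),
               runif(n_ped, -1000, 1000))
      p <- pmin(pmax(1L, a + as.integer(round(off))), genome[[cm]])
      add(p, rep(cm, length(p)), 1L + rgeom(length(p), 0.6))  # recurrent flank breaks
    }
    # TSS protection: every expressed promoter shields breakage in its core,
    # so all non-hot-spot sites are thinned by a linear ramp in the distance
    # to the nearest expressed TSS (zero survival at the TSS itself)
    for (cm in unique(chr)) {
      ai <- sort(start(anchors)[as.character(seqnames(anchors)) == cm])
      if (!length(ai)) next
      si <- which(chr == cm)
      j <- findInterval(pos[si], ai)
      d_lo <- ifelse(j >= 1, pos[si] - ai[pmax(j, 1L)], Inf)
      d_hi <- ifelse(j < length(ai), ai[pmin(j + 1L, length(ai))] - pos[si], Inf)
      d <- pmin(d_lo, d_hi)
      drop <- runif(length(si)) >= pmin(1, d / tss_dip_halfwidth)
      if (any(drop)) {
        rm_idx <- si[drop]
        pos <- pos[-rm_idx]; chr <- chr[-rm_idx]; cnt <- cnt[-rm_idx]
      }
    }
  }

  # 4. hot-spot tiles at domain boundaries
  hot_tiles <- GRanges(seqinfo = as_seqinfo(genome))
  if (hotspot_fold > 0) {
    reads_per_tile <- max(1, round(hotspot_fold * max(1, bg_tile_reads)))
    reps_gr <- ledger$repeat_ranges
    for (cm in chroms) {
      x <- round(runif(1, 0, mean(hotspot_domain_len)))
      while (x + 1000 < genome[[cm]]) {
        tile_start <- as.integer(x - x %% 1000 + 1L)   # align to the 1-kb grid
        # domain-delimiting hot spots sit in unique (non-repeat) sequence;
        # nudge a boundary off any repeat so repeat filtering cannot eat it
        tile <- NULL
        tries <- 0L
        while (tile_start + 999L <= genome[[cm]]) {
          tile <- GRanges(cm, IRanges(tile_start, tile_start + 999L),
                          seqinfo = as_seqinfo(genome))
          if (is.null(reps_gr) || !length(findOverlaps(tile, reps_gr)) ||
              tries >= 50L) break
          tile <- NULL
          tile_start <- tile_start + 1000L
          tries <- tries + 1L
        }
        if (is.null(tile)) break
        hot_tiles <- c(hot_tiles, tile)
        n_sites <- 3L + rpois(1, 7)
        p <- tile_start + sample.int(1000L, n_sites, replace = TRUE) - 1L
        k <- as.vector(stats::rmultinom(1, reads_per_tile, rep(1, n_sites)))
        add(p[k > 0], rep(cm, sum(k > 0)), k[k > 0])
        x <- max(x, tile_start) + runif(1, hotspot_domain_len[1], hotspot_domain_len[2])
      }
    }
  }

  latent <- site_set(GRanges(chr, IRanges(pos, width = 1L), count = cnt,
                             seqinfo = as_seqinfo(genome)))
  thin <- function(s) {
    k <- rbinom(length(s), s$count, 1 - noise)
    s$count <- k
    s[k > 0]
  }
  rep1 <- thin(latent)
  rep2 <- thin(latent)
  ledger$dsb_params <- list(background_rate = background_rate,
                            gene_enrichment = gene_enrichment,
                            tss_flank_enrichment = tss_flank_enrichment,
                            tss_dip_halfwidth = tss_dip_halfwidth,
                            hotspot_domain_len = hotspot_domain_len,
                            hotspot_fold = hotspot_fold, noise = noise,
                            seed = seed)
  ledger$dsb_target_genes <- target_ids
  ledger$silent_genes <- silent_plan
  ledger$expressed_genes <- expressed
  ledger$flank_anchors <- data.frame(
    gene_id = anchors$gene_id,
    seqnames = as.character(seqnames(anchors)),
    position = start(anchors),
    strand = as.character(strand(anchors)))
  ledger$hotspot_tiles <- sort(hot_tiles)
  list(rep1 = rep1, rep2 = rep2, ledger = ledger)
}

#' Generate 4C contact sites partially co-located with DSB-target genes
#'
#' Plants strong contact-site clusters in a gene list of the same size as
#' the DSB-target list, sharing `overlap_with_dsb_genes` of its members, on
#' top of a uniform contact background, so the top contact-ranked genes
#' overlap the DSB-target genes at the stated fraction.
#'
#' @param ann a `GeneAnnotation`.
#' @param ledger ledger carrying `dsb_target_genes`.
#' @param overlap_with_dsb_genes fraction in [0, 1] (default 0.36).
#' @param background_rate background contacts per Mb (default 200).
#' @param seed RNG seed.
#' @return list with `contacts` (site-set `GRanges`) and updated `ledger`
#'   (field `contact_target_genes`).
#' @export
make_contact_sites <- function(ann, ledger, overlap_with_dsb_genes = 0.36,
                               background_rate = 200, seed = 42L) {
  if (overlap_with_dsb_genes < 0 || overlap_with_dsb_genes > 1)
    stop("overlap fraction must be in [0, 1]")
  set.seed(seed + 2L)
  genome <- ann$genome
  genes <- ann$genes
  dsb <- ledger$dsb_target_genes
  if (is.null(dsb)) stop("ledger lacks dsb_target_genes; run make_dsb_replicates first")
  n <- length(dsb)
  n_shared <- round(overlap_with_dsb_genes * n)
  others <- setdiff(genes$gene_id, dsb)
  if (n - n_shared > length(others))
    stop("infeasible overlap fraction for the available gene count")
  targets <- sort(c(sample(dsb, n_shared), sample(others, n - n_shared)))

  pos <- integer(0); chr <- character(0); cnt <- integer(0)
  for (cm in names(genome)) {
    n_bg <- rpois(1, background_rate * genome[[cm]] / 1e6)
    pos <- c(pos, sample.int(genome[[cm]], n_bg, replace = TRUE))
    chr <- c(chr, rep(cm, n_bg))
    cnt <- c(cnt, 1L + rgeom(n_bg, 0.6))
  }
  tg <- genes[genes$gene_id %in% targets]
  for (i in seq_along(tg)) {
    k <- 30L + rpois(1, 20)
    p <- start(tg)[i] + sample.int(width(tg)[i], k, replace = TRUE) - 1L
    pos <- c(pos, p)
    chr <- c(chr, rep(as.character(seqnames(tg)[i]), k))
    cnt <- c(cnt, 1L + rgeom(k, 0.5))
  }
  contacts <- site_set(GRanges(chr, IRanges(as.integer(pos), width = 1L),
                               count = as.integer(cnt),
                               seqinfo = as_seqinfo(genome)),
                       label = "4C")
  ledger$contact_target_genes <- targets
  ledger$contact_params <- list(overlap_with_dsb_genes = overlap_with_dsb_genes,
                                background_rate = background_rate, seed = seed)
  list(contacts = contacts, ledger = ledger)
}

#' Generate a TPM expression table and per-TSS CAGE values
#'
#' A planted fraction of genes is silent (TPM uniform in [0, 0.01]); the
#' rest are log-normal.  Planted DSB-target genes get a multiplicative
#' `2^dsb_gene_shift` TPM shift.  Each expressed gene gets a major TSS at
#' its annotated start with CAGE value proportional to TPM; a fraction of
#' genes (never planted bidirectional-pair members) also get alternative
#' TSSs whose CAGE values are planted deliberately below and above the 5%
#' minor-TSS threshold.
#'
#' @param genes a `GeneAnnotation` or a character vector of gene ids (the
#'   latter yields a table without TSS/CAGE records, for pure
#'   expression-statistics work).
#' @param ledger ledger (optional when `genes` is a character vector);
#'   `silent_genes` and `dsb_target_genes` are honoured when present.
#' @param silent_frac fraction of silent genes (default 0.4), used when the
#'   ledger does not already fix the silent set.
#' @param meanlog,sdlog log-normal parameters of expressed TPM (defaults 1, 1.5).
#' @param dsb_gene_shift log2 TPM shift planted on DSB-target genes (default 2).
#' @param minor_frac the minor-TSS threshold the CAGE planting brackets
#'   (default 0.05).
#' @param seed RNG seed.
#' @return list with `expr` (data.frame `gene_id`, `tpm`), `tss` (TSS record
#'   data.frame or NULL), and updated `ledger` (fields `silent_genes`,
#'   `tpm_shift_log2`, `planted_minor_tss`, `planted_kept_alt_tss`).
#' @export
make_expression_table <- function(genes, ledger = list(), silent_frac = 0.4,
                                  meanlog = 1, sdlog = 1.5, dsb_gene_shift = 2,
                                  minor_frac = 0.05, seed = 42L) {
  set.seed(seed + 3L)
  ann <- NULL
  if (inherits(genes, "GeneAnnotation")) {
    ann <- genes
    ids <- ann$genes$gene_id
  } else ids <- as.character(genes)
  n <- length(ids)
  targets <- ledger$dsb_target_genes
  silent <- ledger$silent_genes
  if (is.null(silent)) {
    protect <- unique(c(targets,
                        ledger$planted_pairs$minus_gene,
                        ledger$planted_pairs$plus_gene))
    pool <- setdiff(ids, protect)
    n_sil <- round(silent_frac * n)
    if (n_sil > length(pool)) {
      extra <- sample(intersect(ids, protect), n_sil - length(pool))
      silent <- sort(c(pool, extra))
    } else silent <- sort(sample(pool, n_sil))
  }
  tpm <- stats::setNames(numeric(n), ids)
  tpm[silent] <- runif(length(silent), 0, 0.01)
  expressed <- setdiff(ids, silent)
  v <- rlnorm(length(expressed), meanlog, sdlog)
  v[v <= 0.011] <- 0.012        # keep the silent window exclusive to silent genes
  tpm[expressed] <- v
  if (!is.null(targets) && dsb_gene_shift != 0) {
    up <- intersect(expressed, targets)
    tpm[up] <- tpm[up] * 2^dsb_gene_shift
  }
  expr <- data.frame(gene_id = ids, tpm = as.numeric(tpm))

  tss <- NULL
  planted_minor <- character(0)
  planted_kept <- character(0)
  if (!is.null(ann)) {
    g <- ann$genes
    tss0 <- GenomicRanges::promoters(g, 0, 1)
    rows <- list()
    pair_members <- unique(c(ledger$planted_pairs$minus_gene,
                             ledger$planted_pairs$plus_gene))
    for (i in seq_along(g)) {
      id <- g$gene_id[i]
      major_cage <- if (tpm[id] > 0.01) tpm[id] * 10 * runif(1, 0.8, 1.25) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        tss_id = paste0(id, ".tss1"), gene_id = id,
        seqnames = as.character(seqnames(tss0)[i]),
        position = start(tss0)[i], strand = as.character(strand(g)[i]),
        cage = major_cage)
      # alternative downstream TSSs, never on planted pair members
      if (major_cage > 0 && !(id %in% pair_members) && runif(1) < 0.3) {
        delta <- sample(200:1500, 1)
        p <- if (as.character(strand(g)[i]) == "+") start(tss0)[i] + delta
             else start(tss0)[i] - delta
        is_minor <- runif(1) < 0.5
        frac <- if (is_minor) runif(1, 0.2, 0.8) * minor_frac
                else runif(1, 1.5, 8) * minor_frac
        alt_id <- paste0(id, ".tss2")
        rows[[length(rows) + 1L]] <- data.frame(
          tss_id = alt_id, gene_id = id,
          seqnames = as.character(seqnames(tss0)[i]),
          position = as.integer(p), strand = as.character(strand(g)[i]),
          cage = major_cage * frac)
        if (is_minor) planted_minor <- c(planted_minor, alt_id)
        else planted_kept <- c(planted_kept, alt_id)
      }
    }
    tss <- do.call(rbind, rows)
  }
  ledger$silent_genes <- silent
  ledger$tpm_shift_log2 <- dsb_gene_shift
  ledger$planted_minor_tss <- planted_minor
  ledger$planted_kept_alt_tss <- planted_kept
  ledger$expr_params <- list(silent_frac = silent_frac, meanlog = meanlog,
                             sdlog = sdlog, seed = seed)
  list(expr = expr, tss = tss, ledger = ledger)
}

#' Generate epigenetic-style signal tracks with planted peaks
#'
#' Each mark is a smooth positive background (baseline plus a slow
#' sinusoidal modulation) with Gaussian bumps added at the midpoints of a
#' designated anchor class (`dsb` = planted hot-spot tiles, `contacts` =
#' contact-target gene centres) and, optionally, negative bumps (depletion)
#' at a second class.  Tracks are piecewise constant at 20-bp resolution.
#'
#' @param ann a `GeneAnnotation`.
#' @param ledger ledger carrying `hotspot_tiles` / `contact_target_genes`.
#' @param marks data.frame with columns `name`, `enriched_at`, `depleted_at`
#'   (each of `"dsb"`, `"contacts"`, `"none"`), `peak_height`, `peak_width`.
#'   Default: one DSB-enriched/contact-depleted mark, one the reverse, one flat.
#' @param seed RNG seed.
#' @return list of signal-track `GRanges`, named by mark.
#' @export
make_signal_tracks <- function(ann, ledger, marks = NULL, seed = 42L) {
  set.seed(seed + 4L)
  if (is.null(marks))
    marks <- data.frame(
      name = c("mark_dsb", "mark_contact", "mark_flat"),
      enriched_at = c("dsb", "contacts", "none"),
      depleted_at = c("contacts", "dsb", "none"),
      peak_height = c(3, 3, 0),
      peak_width = c(400, 400, 400))
  if (any(marks$peak_width <= 0)) stop("peak widths must be > 0")
  genome <- ann$genome
  res <- 20L
  anchor_mid <- function(class) {
    if (class == "dsb") {
      ht <- ledger$hotspot_tiles
      if (is.null(ht) || !length(ht)) return(NULL)
      data.frame(chr = as.character(seqnames(ht)),
                 mid = start(ht) + width(ht) %/% 2L)
    } else if (class == "contacts") {
      tg <- ann$genes[ann$genes$gene_id %in% ledger$contact_target_genes]
      if (!length(tg)) return(NULL)
      data.frame(chr = as.character(seqnames(tg)),
                 mid = start(tg) + width(tg) %/% 2L)
    } else NULL
  }
  out <- list()
  for (k in seq_len(nrow(marks))) {
    trk <- list()
    for (cm in names(genome)) {
      nseg <- as.integer(ceiling(genome[[cm]] / res))
      x <- seq_len(nseg) * res - res / 2
      # blocky slow background (constant within 2-kb blocks) so that runs of
      # equal values collapse in the Rle representation
      blk <- (seq_len(nseg) - 1L) %/% 100L + 1L
      xb <- unique(blk) * 100 * res - 1000
      bg <- 1 + 0.3 * sin(2 * pi * xb / 1e5 + runif(1, 0, 2 * pi))
      v <- bg[blk]
      for (dir in c("enriched_at", "depleted_at")) {
        am <- anchor_mid(marks[[dir]][k])
        if (is.null(am)) next
        sgn <- if (dir == "enriched_at") 1 else -1
        h <- sgn * marks$peak_height[k]
        s <- marks$peak_width[k] / 2
        for (m in am$mid[am$chr == cm]) {
          lo <- max(1L, as.integer((m - 3 * s) %/% res)); hi <- min(nseg, as.integer((m + 3 * s) %/% res) + 1L)
          if (lo > hi) next
          v[lo:hi] <- v[lo:hi] + h * exp(-((x[lo:hi] - m)^2) / (2 * s^2))
        }
      }
      r <- Rle(v, rep(res, nseg))
      r <- r[seq_len(genome[[cm]])]   # clip to the chromosome
      trk[[cm]] <- r
    }
    gr <- methods::as(methods::as(trk, "SimpleRleList"), "GRanges")
    seqinfo(gr) <- as_seqinfo(genome)
    out[[marks$name[k]]] <- sort(gr, ignore.strand = TRUE)
  }
  out
}

#' Run the whole synthetic-study generator (demo preset)
#'
#' Chains [make_genome()], [make_dsb_replicates()], [make_contact_sites()],
#' [make_expression_table()] and [make_signal_tracks()] with a single seed,
#' threading the planted-truth ledger through all stages.  The default demo
#' scale is 2 chromosomes of 5 Mb, 400 genes and two DSB replicates of
#' roughly 20k sites.
#'
#' @param seed RNG seed (default 42).
#' @param ... overrides forwarded to the generators (matched by name).
#' @return list with `ann`, `repeats`, `genome`, `rep1`, `rep2`, `contacts`,
#'   `expr`, `tss`, `tracks`, `ledger`.
#' @export
simulate_dsb_study <- function(seed = 42L, ...) {
  dots <- list(...)
  pick <- function(f) dots[intersect(names(dots), names(formals(f)))]
  g <- do.call(make_genome, c(list(seed = seed), pick(make_genome)))
  d <- do.call(make_dsb_replicates,
               c(list(ann = g$ann, ledger = g$ledger, seed = seed),
                 pick(make_dsb_replicates)))
  cc <- do.call(make_contact_sites,
                c(list(ann = g$ann, ledger = d$ledger, seed = seed),
                  pick(make_contact_sites)))
  e <- do.call(make_expression_table,
               c(list(genes = g$ann, ledger = cc$ledger, seed = seed),
                 pick(make_expression_table)))
  tracks <- do.call(make_signal_tracks,
                    c(list(ann = g$ann, ledger = e$ledger, seed = seed),
                      pick(make_signal_tracks)))
  list(ann = g$ann, repeats = g$repeats, genome = g$genome,
       rep1 = d$rep1, rep2 = d$rep2, contacts = cc$contacts,
       expr = e$expr, tss = e$tss, tracks = tracks, ledger = e$ledger)
}
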