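# Adapter gating, replicate intersection, repeat filtering, tiling,
# hot-spot selection, quartiles, coverage and correlation.

fastq_df <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- vapply(seqs, function(s)
    strrep("I", nchar(s)), "")   # 'I' = Q40
  data.frame(id = sprintf("r%d", seq_along(seqs)), sequence = seqs,
             quality = quals, row.names = NULL)
}

test_that("FASTQ files round into the read table used by adapter gating", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "TTTT", "+", "++++"), f)
  rd <- read_fastq(f)
  expect_equal(rd$id, c("r1", "r2"))
  expect_equal(rd$sequence, c("ACGTACGT", "TTTT"))
  expect_equal(rd$quality, c("IIIIIIII", "++++"))
})

test_that("reads lacking the mandatory adapter are discarded and inserts trimmed", {
  ad <- "CCGAATTCTCC"
  reads <- fastq_df(c(
    paste0(ad, strrep("ACGT", 7)),          # 28-nt insert, kept
    strrep("ACGT", 12),                     # no adapter, discarded
    paste0(ad, strrep("AC", 5))))           # 10-nt insert, too short
  out <- filter_reads_by_adapter(reads, ad, min_len = 20, min_quality = 26)
  expect_equal(out$id, "r1")
  expect_equal(out$sequence, strrep("ACGT", 7))
  expect_error(filter_reads_by_adapter(reads, ""), "non-empty")
})

test_that("low-quality 3' tails are trimmed before the length check", {
  ad <- "CCGAATTCTCC"
  insert <- strrep("ACGT", 8)               # 32 nt
  # last 15 bases at Q10 ('+'), rest Q40: surviving insert 17 < 20 -> dropped
  qual <- paste0(strrep("I", nchar(ad) + 17), strrep("+", 15))
  reads <- fastq_df(paste0(ad, insert), qual)
  expect_equal(nrow(filter_reads_by_adapter(reads, ad)), 0L)
  # only 5 low-quality tail bases: 27 nt remain -> kept, trimmed
  qual2 <- paste0(strrep("I", nchar(ad) + 27), strrep("+", 5))
  out <- filter_reads_by_adapter(fastq_df(paste0(ad, insert), qual2), ad)
  expect_equal(nchar(out$sequence), 27L)
})

test_that("replicate intersection takes the per-segment minimum count", {
  genome <- c(chr1 = 1000L)
  r1 <- site_set(GRanges("chr1", IRanges(1, 100), count = 5L), genome)
  r2 <- site_set(GRanges("chr1", IRanges(51, 150), count = 3L), genome)
  out <- intersect_replicates(r1, r2)
  expect_equal(start(out), 51L)
  expect_equal(end(out), 100L)
  expect_equal(out$count, 3L)
  # disjoint replicates
  r3 <- site_set(GRanges("chr1", IRanges(500, 600), count = 2L), genome)
  expect_length(intersect_replicates(r1, r3), 0L)
})

test_that("replicate intersection equals the per-base oracle on random input", {
  set.seed(202)
  for (i in 1:10) {
    r1 <- random_sites(30)
    r2 <- random_sites(30)
    got <- intersect_replicates(r1, r2)
    expect_identical(as_base_vector(got), oracle_intersect(r1, r2))
  }
})

test_that("sites fully inside repeats are removed, partial overlaps retained", {
  genome <- c(chr1 = 10000L)
  sites <- site_set(GRanges("chr1", IRanges(c(100, 300, 700), width = 50),
                            count = c(1L, 1L, 1L)), genome)
  repeats <- site_set(GRanges("chr1", IRanges(c(80, 320), c(200, 500)),
                              count = c(1L, 1L)), genome)
  out <- remove_repeat_contained(sites, repeats)
  # site at 100-149 contained, 300-349 partial, 700-749 clear
  expect_equal(start(out), c(300L, 700L))
})

test_that("tile_counts bins by site midpoint and matches the naive oracle", {
  genome <- c(chr1 = 5000L)
  sites <- site_set(GRanges("chr1", IRanges(c(11, 501, 1501), width = 1),
                            count = c(2L, 3L, 4L)), genome)
  tl <- tile_counts(sites, 1000)
  expect_equal(tl$count, c(5L, 4L))
  expect_equal(start(tl), c(1L, 1001L))
  # empty input -> zero tiles omitted
  empty <- site_set(GRanges(), genome)
  expect_length(tile_counts(empty, 1000), 0L)
  # random oracle: per-site midpoint binning
  set.seed(303)
  for (i in 1:10) {
    s <- random_sites(100)
    got <- tile_counts(s, 1000)
    mid <- start(s) + (width(s) - 1L) %/% 2L
    key <- paste(seqnames(s), (mid - 1L) %/% 1000L)
    exp_counts <- tapply(s$count, key, sum)
    got_key <- paste(seqnames(got), (start(got) - 1L) %/% 1000L)
    expect_setequal(got_key, names(exp_counts))
    expect_equal(got$count[match(names(exp_counts), got_key)],
                 as.integer(exp_counts), ignore_attr = TRUE)
  }
})

test_that("select_top_fraction keeps the top fraction with ties included", {
  genome <- c(chr1 = 1000000L)
  tiles <- site_set(GRanges("chr1", IRanges((0:199) * 1000 + 1, width = 1000),
                            count = as.integer(sample(1:200))), genome)
  hs <- select_top_fraction(tiles, 0.025)
  expect_length(hs$tiles, 5L)
  expect_setequal(hs$tiles$count, 196:200)
  # tie rule: all tiles tied with the cutoff retained
  t2 <- site_set(GRanges("chr1", IRanges(c(1, 1001, 2001, 3001), width = 1000),
                         count = c(10L, 10L, 10L, 1L)), genome)
  hs2 <- select_top_fraction(t2, 0.25)
  expect_length(hs2$tiles, 3L)
  expect_true(all(hs2$tiles$count == 10L))
  # frac = 1 keeps every nonzero tile
  expect_length(select_top_fraction(t2, 1)$tiles, 4L)
  expect_error(select_top_fraction(t2, 0), "frac")
})

test_that("quartile stratification partitions the input with ties promoted upward", {
  genome <- c(chr1 = 1000000L)
  s <- site_set(GRanges("chr1", IRanges(seq(1, by = 10, length.out = 100), width = 1),
                        count = as.integer(sample(1:100))), genome)
  q <- stratify_quartiles(s)
  expect_equal(vapply(q, length, 0L), c(Q1 = 25L, Q2 = 25L, Q3 = 25L, Q4 = 25L))
  expect_equal(sum(vapply(q, length, 0L)), length(s))
  expect_true(min(q$Q1$count) > max(q$Q2$count))
  # all counts equal: everything lands in Q1 under the tie rule
  s2 <- site_set(GRanges("chr1", IRanges(c(1, 11, 21), width = 1),
                         count = c(7L, 7L, 7L)), genome)
  q2 <- stratify_quartiles(s2)
  expect_length(q2$Q1, 3L)
  expect_length(q2$Q4, 0L)
  # sort-based oracle on random counts: quartile of a site only depends on
  # count thresholds at the boundary ranks
  set.seed(404)
  for (i in 1:5) {
    s3 <- random_sites(57)
    q3 <- stratify_quartiles(s3)
    cs <- sort(s3$count, decreasing = TRUE)
    thr <- cs[ceiling(57 * (1:3) / 4)]
    expect_equal(length(q3$Q1), sum(s3$count >= thr[1]))
    expect_equal(length(q3$Q1) + length(q3$Q2), sum(s3$count >= thr[2]))
    expect_equal(sum(vapply(q3, length, 0L)), 57L)
  }
  expect_error(stratify_quartiles(site_set(GRanges(), genome)), "empty")
})

test_that("RPKM normalisation follows count / (kb * libsize/1e6)", {
  genome <- c(chr1 = 1e6)
  # 1000-bp segment with count 10 in a library of 1e6 reads -> RPKM 10
  reps <- list(
    site_set(GRanges("chr1", IRanges(c(1, 2001), c(1000, 3000)),
                     count = c(10L, 999990L)), genome),
    site_set(GRanges("chr1", IRanges(c(1, 2001), c(1000, 3000)),
                     count = c(10L, 999990L)), genome))
  tr <- normalized_mean_coverage(reps, "rpkm")
  expect_equal(tr$score[start(tr) == 1], 10)
  # identical replicates: mean equals each replicate
  one <- normalized_mean_coverage(reps[1], "rpkm")
  expect_equal(tr$score, one$score)
  # RPKM conservation: sum(value * length_kb) == 1e6 when every read is in a segment
  expect_equal(sum(tr$score * width(tr) / 1000), 1e6)
  expect_error(normalized_mean_coverage(list(), "rpkm"), "at least one")
})

test_that("mean coverage across two random replicates equals the per-base (sum/2) oracle", {
  set.seed(505)
  r1 <- random_sites(40); r2 <- random_sites(40)
  tr <- normalized_mean_coverage(list(r1, r2), "none")
  base <- mapply(function(a, b) (a + b) / 2, as_base_vector(r1), as_base_vector(r2),
                 SIMPLIFY = FALSE)
  got <- as_base_vector({x <- tr; x$count <- x$score; x})
  expect_equal(got, base)
})

test_that("replicate correlation is 1 for identical tracks, -1 rho for monotone inversion", {
  genome <- c(chr1 = 10000L)
  t1 <- signal_track(GRanges("chr1", IRanges(seq(1, 9001, by = 1000), width = 1000),
                             score = as.numeric(1:10)), genome)
  expect_equal(unname(replicate_correlation(t1, t1, 1000)), c(1, 1))
  t2 <- t1; t2$score <- 1 / t1$score
  expect_equal(unname(replicate_correlation(t1, t2, 1000)[2]), -1)
  # hand-computed coefficients on 20 bins
  v1 <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2, 3, 8, 4)
  v2 <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8, 4, 5, 9, 0, 4, 5, 2, 3, 5, 3)
  g2 <- c(chr1 = 20000L)
  tt1 <- signal_track(GRanges("chr1", IRanges(seq(1, by = 1000, length.out = 20),
                                              width = 1000), score = v1), g2)
  tt2 <- signal_track(GRanges("chr1", IRanges(seq(1, by = 1000, length.out = 20),
                                              width = 1000), score = v2), g2)
  rc <- replicate_correlation(tt1, tt2, 1000)
  expect_equal(unname(rc[1]), cor(v1, v2))
  expect_equal(unname(rc[2]), cor(v1, v2, method = "spearman"))
  # zero-variance track reported as NA, not 0
  t0 <- signal_track(GRanges("chr1", IRanges(1, 10000), score = 2), genome)
  expect_warning(rc0 <- replicate_correlation(t0, t1, 1000), "zero-variance")
  expect_true(all(is.na(rc0)))
})

test_that("repeat filtering and replicate intersection commute for 1-bp sites", {
  set.seed(606)
  genome <- toy_genome
  mk <- function() {
    n <- 300
    chr <- sample(names(genome), n, replace = TRUE)
    p <- vapply(chr, function(cm) sample.int(genome[[cm]], 1), integer(1))
    site_set(GRanges(chr, IRanges(p, width = 1),
                     count = sample.int(5, n, replace = TRUE)), genome)
  }
  r1 <- mk(); r2 <- mk()
  repeats <- random_sites(40, max_width = 2000)
  a <- intersect_replicates(remove_repeat_contained(r1, repeats),
                            remove_repeat_contained(r2, repeats))
  b <- remove_repeat_contained(intersect_replicates(r1, r2), repeats)
  expect_identical(as_base_vector(a), as_base_vector(b))
})
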