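# TSS preparation, bidirectional promoter classification and TSS profiles.

mk_tss <- function(...) do.call(tss_records, list(...))

test_that("silent and minor TSSs are removed, boundary is strict", {
  tss <- mk_tss(tss_id = c("t1", "t2", "t3", "t4", "t5"),
                gene_id = c("g1", "g1", "g2", "g2", "g3"),
                seqnames = "chr1", position = c(100, 500, 900, 1300, 2000),
                strand = "+", cage = c(100, 4, 100, 5, 0))
  out <- prepare_tss_list(tss)
  # g1: 4 < 5% of 100 -> removed; g2: 5 == 5% -> kept ("less than" is strict)
  expect_setequal(out$tss_id, c("t1", "t3", "t4"))
  # zero-CAGE t5 removed
  expect_false("t5" %in% out$tss_id)
  # idempotence
  expect_identical(prepare_tss_list(out), out)
  # exact duplicates removed
  dup <- rbind(tss[1, ], tss)
  expect_equal(nrow(prepare_tss_list(dup)), 3L)
  # cage supplied as a named map; missing ids treated as silent with warning
  cg <- c(t1 = 50, t2 = 50, t3 = 10, t4 = 10)
  expect_warning(out2 <- prepare_tss_list(tss, cage = cg), "silent")
  expect_setequal(out2$tss_id, c("t1", "t2", "t3", "t4"))
})

test_that("divergent pairs under 1 kb are classified bidirectional", {
  tss <- mk_tss(tss_id = c("m", "p"), gene_id = c("gm", "gp"),
                seqnames = "chr1", position = c(4500, 5000),
                strand = c("-", "+"), cage = c(10, 10))
  pc <- classify_promoter_directionality(tss, 1000)
  expect_equal(nrow(pc$bidirectional), 1L)
  expect_equal(pc$bidirectional$distance, 500L)
  expect_equal(nrow(pc$unidirectional), 0L)
  # distance 1500: both unidirectional
  tss2 <- mk_tss(tss_id = c("m", "p"), gene_id = c("gm", "gp"),
                 seqnames = "chr1", position = c(4500, 6000),
                 strand = c("-", "+"), cage = c(10, 10))
  pc2 <- classify_promoter_directionality(tss2, 1000)
  expect_equal(nrow(pc2$bidirectional), 0L)
  expect_equal(nrow(pc2$unidirectional), 2L)
  # convergent orientation (plus left of minus): unidirectional
  tss3 <- mk_tss(tss_id = c("p", "m"), gene_id = c("gp", "gm"),
                 seqnames = "chr1", position = c(4500, 5000),
                 strand = c("+", "-"), cage = c(10, 10))
  expect_equal(nrow(classify_promoter_directionality(tss3, 1000)$bidirectional), 0L)
  # different chromosomes never pair
  tss4 <- mk_tss(tss_id = c("m", "p"), gene_id = c("gm", "gp"),
                 seqnames = c("chr1", "chr2"), position = c(4500, 5000),
                 strand = c("-", "+"), cage = c(10, 10))
  expect_equal(nrow(classify_promoter_directionality(tss4, 1000)$bidirectional), 0L)
})

test_that("chained candidates pair with the nearest partner; no TSS in both lists", {
  # A- at 1000, B+ at 1600, C- at 2100: B pairs with A (600 < 1100 invalid C-B?
  # C at 2100 is right of B so (C,B) is convergent; add D+ at 2900 for C
  tss <- mk_tss(tss_id = c("A", "B", "C", "D"),
                gene_id = c("gA", "gB", "gC", "gD"),
                seqnames = "chr1", position = c(1000, 1600, 2100, 2900),
                strand = c("-", "+", "-", "+"), cage = 10)
  pc <- classify_promoter_directionality(tss, 1000)
  expect_equal(sort(paste(pc$bidirectional$minus_tss_id,
                          pc$bidirectional$plus_tss_id)),
               c("A B", "C D"))
  expect_true(all(!pc$unidirectional$tss_id %in%
                    c(pc$bidirectional$minus_tss_id, pc$bidirectional$plus_tss_id)))
  # greedy nearest-partner: B+ at 500 with A- at 100 and Z- at 480:
  # Z-B distance 20 wins, A stays unidirectional
  tss2 <- mk_tss(tss_id = c("A", "Z", "B"), gene_id = c("gA", "gZ", "gB"),
                 seqnames = "chr1", position = c(100, 480, 500),
                 strand = c("-", "-", "+"), cage = 10)
  pc2 <- classify_promoter_directionality(tss2, 1000)
  expect_equal(pc2$bidirectional$minus_tss_id, "Z")
  expect_setequal(pc2$unidirectional$tss_id, "A")
})

test_that("classification is invariant under genome mirroring", {
  set.seed(21)
  n <- 60
  tss <- mk_tss(tss_id = sprintf("t%02d", 1:n), gene_id = sprintf("g%02d", 1:n),
                seqnames = "chr1",
                position = sort(sample.int(50000, n)),
                strand = sample(c("+", "-"), n, replace = TRUE), cage = 10)
  pc <- classify_promoter_directionality(tss, 1000)
  L <- 60001
  mir <- tss
  mir$position <- L - tss$position
  mir$strand <- ifelse(tss$strand == "+", "-", "+")
  pcm <- classify_promoter_directionality(mir, 1000)
  # the pair sets map onto each other (minus/plus roles swap)
  orig <- sort(paste(pc$bidirectional$minus_tss_id, pc$bidirectional$plus_tss_id))
  mirr <- sort(paste(pcm$bidirectional$plus_tss_id, pcm$bidirectional$minus_tss_id))
  expect_equal(orig, mirr)
  expect_setequal(pc$unidirectional$tss_id, pcm$unidirectional$tss_id)
})

test_that("the classifier recovers exactly the generator's planted pairs", {
  for (s in c(3, 14)) {
    sim <- simulate_dsb_study(seed = s)
    prep <- prepare_tss_list(sim$tss)
    pc <- classify_promoter_directionality(prep, 1000)
    got <- sort(paste(pc$bidirectional$minus_tss_id, pc$bidirectional$plus_tss_id))
    planted <- sort(paste(paste0(sim$ledger$planted_pairs$minus_gene, ".tss1"),
                          paste0(sim$ledger$planted_pairs$plus_gene, ".tss1")))
    expect_equal(got, planted)
    expect_length(intersect(pc$unidirectional$tss_id,
                            c(pc$bidirectional$minus_tss_id,
                              pc$bidirectional$plus_tss_id)), 0L)
  }
})

test_that("minor-TSS filtering matches the planted below/above-threshold labels", {
  sim <- simulate_dsb_study(seed = 6)
  prep <- prepare_tss_list(sim$tss, minor_frac = 0.05)
  expect_length(intersect(prep$tss_id, sim$ledger$planted_minor_tss), 0L)
  expect_true(all(sim$ledger$planted_kept_alt_tss %in% prep$tss_id))
})

test_that("TSS profiles are symmetric for mirror-symmetric sites and strand-invariant", {
  genome <- c(chr1 = 100000L)
  anchors <- mk_tss(tss_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                    seqnames = "chr1", position = c(20000, 60000),
                    strand = c("+", "-"), cage = 10)
  offs <- c(-295, -145, 145, 295)   # bin-centre offsets mirror exactly
  pos <- c(20000 + offs, 60000 + offs)
  sites <- site_set(GRanges("chr1", IRanges(pos, width = 1),
                            count = rep(2L, length(pos))), genome)
  pro <- tss_signal_profile(sites, anchors, span = 1000, bin = 10)
  expect_length(pro$values, 200L)
  expect_equal(pro$values, rev(pro$values), tolerance = 1e-9)
  # flipping every anchor strand leaves a symmetric profile unchanged
  flipped <- anchors
  flipped$strand <- ifelse(anchors$strand == "+", "-", "+")
  pro2 <- tss_signal_profile(sites, flipped, span = 1000, bin = 10)
  expect_equal(pro$values, pro2$values)
  expect_error(tss_signal_profile(sites, anchors[0, ], 1000, 10), "empty")
  expect_error(tss_signal_profile(sites, anchors, span = 1005, bin = 10), "multiple")
})

test_that("profiles recover the planted dip and +/-300 bp flank maxima", {
  sim <- simulate_dsb_study(seed = 8)
  both <- intersect_replicates(remove_repeat_contained(sim$rep1, sim$repeats),
                               remove_repeat_contained(sim$rep2, sim$repeats))
  fa <- sim$ledger$flank_anchors
  anchors <- tss_records(paste0(fa$gene_id, ".t"), fa$gene_id, fa$seqnames,
                         fa$position, fa$strand, 1)
  pro <- tss_signal_profile(both, anchors, span = 1000, bin = 10)
  expect_lte(abs(profile_extremum(pro, "min")), 15)
  expect_lte(abs(profile_extremum(pro, "max", c(-1000, 0)) + 300), 15)
  expect_lte(abs(profile_extremum(pro, "max", c(0, 1000)) - 300), 15)
})
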