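# Brute-force oracles and fixture builders shared across tests.
suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

toy_genome <- c(chrA = 100000L, chrB = 80000L)

random_sites <- function(n, genome = toy_genome, max_width = 200L,
                         counts = TRUE) {
  chr <- sample(names(genome), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i) sample.int(genome[[chr[i]]] - w[i], 1),
              integer(1))
  gr <- GRanges(chr, IRanges(s, width = w), seqinfo = dsbscape:::as_seqinfo(genome))
  gr$count <- if (counts) sample.int(10, n, replace = TRUE) else rep(1L, n)
  sort(gr, ignore.strand = TRUE)
}

# O(n*m) per-pair overlap-fraction oracle for overlap_query: an interval of a
# is kept iff >= frac of its bases are covered by the union of b
oracle_overlap_keep <- function(a, b, frac) {
  vapply(seq_along(a), function(i) {
    bi <- b[as.character(seqnames(b)) == as.character(seqnames(a)[i])]
    if (!length(bi)) return(FALSE)
    bases <- start(a)[i]:end(a)[i]
    cov <- vapply(bases, function(p) any(start(bi) <= p & end(bi) >= p), logical(1))
    sum(cov) >= frac * length(bases)
  }, logical(1))
}

# per-base replicate intersection oracle: min of the two per-base count sums
oracle_intersect <- function(r1, r2, genome = toy_genome) {
  out <- list()
  for (cm in names(genome)) {
    v1 <- numeric(genome[[cm]]); v2 <- numeric(genome[[cm]])
    for (i in which(as.character(seqnames(r1)) == cm))
      v1[start(r1)[i]:end(r1)[i]] <- v1[start(r1)[i]:end(r1)[i]] + r1$count[i]
    for (i in which(as.character(seqnames(r2)) == cm))
      v2[start(r2)[i]:end(r2)[i]] <- v2[start(r2)[i]:end(r2)[i]] + r2$count[i]
    out[[cm]] <- pmin(v1, v2)
  }
  out
}

as_base_vector <- function(sites, genome = toy_genome) {
  out <- list()
  for (cm in names(genome)) {
    v <- numeric(genome[[cm]])
    for (i in which(as.character(seqnames(sites)) == cm))
      v[start(sites)[i]:end(sites)[i]] <- v[start(sites)[i]:end(sites)[i]] +
        sites$count[i]
    out[[cm]] <- v
  }
  out
}

# small deterministic two-gene annotation on toy_genome
toy_annotation <- function() {
  genes <- GRanges(c("chrA", "chrA", "chrB"),
                   IRanges(c(1001, 20001, 5001), c(5000, 24000, 9000)),
                   strand = c("+", "-", "+"),
                   seqinfo = dsbscape:::as_seqinfo(toy_genome))
  genes$gene_id <- c("g1", "g2", "g3")
  genes$name <- c("G1", "G2", "G3")
  exons <- GRangesList(
    g1 = GRanges("chrA", IRanges(c(1001, 4801), c(1200, 5000))),
    g2 = GRanges("chrA", IRanges(c(20001, 23001), c(21000, 24000))),
    g3 = GRanges("chrB", IRanges(5001, 9000)))
  gene_annotation(genes, exons, toy_genome)
}
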