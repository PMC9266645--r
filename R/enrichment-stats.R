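# Gene-list overlap nulls, Mann-Whitney and Monte-Carlo expression
# comparisons, the averaged random reference sample, silent-gene selection.

#' Gene-list overlap significance under the randomization null
#'
#' Two lists of sizes `nA` and `nB` drawn uniformly without replacement from
#' a universe of `N` genes intersect in a hypergeometrically distributed
#' number of genes.  The exact method evaluates the upper tail with
#' `phyper`; the Monte-Carlo method draws actual list pairs and uses the
#' empirical tail.  `critical_overlap[alpha]` is the smallest overlap k with
#' `P[X >= k] < alpha`.
#'
#' @param nA,nB list sizes.
#' @param N universe size.
#' @param k_obs observed overlap (optional; enables `p_upper`).
#' @param method `"exact"` or `"mc"`.
#' @param reps Monte-Carlo replicates (default 1e5; < 1e4 warns).
#' @param seed RNG seed for the Monte-Carlo path.
#' @param alphas significance levels for critical overlaps.
#' @return object of class `OverlapTestResult`: list with `N`, `nA`, `nB`,
#'   `k_obs`, `expected`, `p_upper`, `critical_overlap` (named numeric),
#'   `method`, `reps`, `seed`.
#' @export
overlap_significance <- function(nA, nB, N, k_obs = NULL,
                                 method = c("exact", "mc"), reps = 1e5,
                                 seed = 42L, alphas = c(0.05, 0.01)) {
  method <- match.arg(method)
  if (nA > N || nB > N || nA < 1 || nB < 1) stop("invalid list/universe sizes")
  if (!is.null(k_obs) && (k_obs < 0 || k_obs > min(nA, nB)))
    stop("k_obs must be in [0, min(nA, nB)]")
  expected <- nA * nB / N
  if (method == "exact") {
    p_up <- function(k) stats::phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
    crit <- vapply(alphas, function(a) {
      k <- max(0L, stats::qhyper(1 - a, nA, N - nA, nB) - 5L)
      while (p_up(k) >= a) k <- k + 1L
      k
    }, numeric(1))
    p_obs <- if (is.null(k_obs)) NA_real_ else p_up(k_obs)
    draws <- NULL
  } else {
    if (reps < 1e4) warning("fewer than 10^4 Monte-Carlo replicates")
    set.seed(seed)
    # exchangeability: fix list A = {1..nA}, draw B without replacement
    draws <- vapply(seq_len(reps),
                    function(i) sum(sample.int(N, nB) <= nA), numeric(1))
    crit <- vapply(alphas, function(a) {
      k <- max(0, stats::quantile(draws, 1 - a, names = FALSE, type = 1) - 5)
      while (mean(draws >= k) >= a) k <- k + 1
      k
    }, numeric(1))
    p_obs <- if (is.null(k_obs)) NA_real_ else mean(draws >= k_obs)
  }
  structure(list(N = N, nA = nA, nB = nB, k_obs = k_obs, expected = expected,
                 p_upper = p_obs,
                 critical_overlap = stats::setNames(crit, as.character(alphas)),
                 method = method,
                 reps = if (method == "mc") reps else NA_integer_,
                 seed = if (method == "mc") seed else NA_integer_,
                 draws = draws),
            class = "OverlapTestResult")
}

#' @export
print.OverlapTestResult <- function(x, ...) {
  cat(sprintf("Overlap null (%s): N=%d, |A|=%d, |B|=%d, E[overlap]=%.1f\n",
              x$method, x$N, x$nA, x$nB, x$expected))
  for (a in names(x$critical_overlap))
    cat(sprintf("  smallest overlap with P[X >= k] < %s: %d\n",
                a, as.integer(x$critical_overlap[[a]])))
  if (!is.null(x$k_obs))
    cat(sprintf("  observed overlap %d: upper-tail p = %.3g\n", x$k_obs, x$p_upper))
  invisible(x)
}

#' Venn summary of two gene lists
#'
#' @param listA,listB character vectors of gene ids (duplicates are dropped
#'   with a warning).
#' @return list with `nA`, `nB`, `n_common`, `pct_of_A`, `pct_of_B`.
#' @export
venn_summary <- function(listA, listB) {
  if (anyDuplicated(listA) || anyDuplicated(listB)) {
    warning("duplicate ids deduplicated")
    listA <- unique(listA); listB <- unique(listB)
  }
  k <- length(intersect(listA, listB))
  list(nA = length(listA), nB = length(listB), n_common = k,
       pct_of_A = 100 * k / length(listA),
       pct_of_B = 100 * k / length(listB))
}

mw_u_stat <- function(x, y) {
  r <- rank(c(x, y))          # midranks for ties
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

mw_exact_p <- function(x, y, U, alternative) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  idx <- utils::combn(n, length(x))
  us <- apply(idx, 2, function(i) sum(r[i])) - length(x) * (length(x) + 1) / 2
  switch(alternative,
         less = mean(us <= U),
         greater = mean(us >= U),
         two.sided = min(1, 2 * min(mean(us <= U), mean(us >= U))))
}

mw_normal_p <- function(x, y, U, alternative) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  ties <- table(c(x, y))
  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(p = 1, z = 0, warn = TRUE))
  cc <- 0.5
  z2 <- switch(alternative,
               less = (U - mu + cc) / sqrt(sigma2),
               greater = (U - mu - cc) / sqrt(sigma2),
               two.sided = (U - mu - sign(U - mu) * cc) / sqrt(sigma2))
  p <- switch(alternative,
              less = stats::pnorm(z2),
              greater = stats::pnorm(z2, lower.tail = FALSE),
              two.sided = 2 * stats::pnorm(-abs(z2)))
  list(p = min(1, p), z = z2, warn = FALSE)
}

#' Mann-Whitney U test for two independent samples
#'
#' U is computed with midranks.  For combined sample sizes up to 12 the null
#' distribution is enumerated exactly over all rank assignments (valid under
#' ties as a permutation test on midranks); larger samples use the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or `"less"`.
#' @return object of class `DistributionTestResult`: list with `U`,
#'   `p_value`, `method`, `alternative`, `nx`, `ny`.
#' @export
mann_whitney_test <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  U <- mw_u_stat(x, y)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical; p = 1")
    res <- list(p = 1, method = "degenerate")
  } else if (length(x) + length(y) <= 12L) {
    res <- list(p = mw_exact_p(x, y, U, alternative), method = "exact-enumeration")
  } else {
    np <- mw_normal_p(x, y, U, alternative)
    res <- list(p = np$p, method = "normal-approximation")
  }
  structure(list(U = U, p_value = res$p, method = res$method,
                 alternative = alternative, nx = length(x), ny = length(y)),
            class = "DistributionTestResult")
}

#' @export
print.DistributionTestResult <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (%d vs %d), %s, p = %.4g [%s]\n",
              x$U, x$nx, x$ny, x$alternative, x$p_value, x$method))
  invisible(x)
}

#' Monte-Carlo expression-distribution test
#'
#' Tests whether the expression of a gene subset could be obtained by drawing
#' genes at random from the full table: each replicate draws a random gene
#' set of the subset's size and compares it with the subset by the
#' Mann-Whitney U test.  Reported are the maximum p over replicates, the
#' fraction of replicates rejecting at `alpha`, and whether all rejected.
#'
#' @param subset_ids gene ids of the subset (must all be in `table`).
#' @param table data.frame with `gene_id` and `tpm` columns.
#' @param reps number of Monte-Carlo replicates (default 10000).
#' @param alpha rejection level per replicate (default 0.05).
#' @param seed RNG seed.
#' @return list of class `McDistributionTest` with `mc_max_p`, `mc_min_p`,
#'   `reject_fraction`, `mc_all_significant`, `reps`, `alpha`, `seed`.
#' @export
mc_distribution_test <- function(subset_ids, table, reps = 10000L,
                                 alpha = 0.05, seed = 42L) {
  stopifnot(all(c("gene_id", "tpm") %in% names(table)))
  if (!all(subset_ids %in% table$gene_id)) stop("subset must be contained in the table")
  m <- length(subset_ids)
  if (m >= nrow(table)) stop("subset size must be smaller than the table")
  set.seed(seed)
  xs <- table$tpm[match(subset_ids, table$gene_id)]
  tpm <- table$tpm
  ps <- vapply(seq_len(reps), function(i) {
    ys <- tpm[sample.int(length(tpm), m)]
    mann_whitney_test(xs, ys)$p_value
  }, numeric(1))
  structure(list(mc_max_p = max(ps), mc_min_p = min(ps),
                 reject_fraction = mean(ps < alpha),
                 mc_all_significant = all(ps < alpha),
                 reps = reps, alpha = alpha, seed = seed),
            class = "McDistributionTest")
}

#' @export
print.McDistributionTest <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo distribution test: %d reps, max p = %.3g, %.1f%% reject at alpha = %g\n",
    x$reps, x$mc_max_p, 100 * x$reject_fraction, x$alpha))
  invisible(x)
}

#' Averaged random reference expression sample
#'
#' Draws `reps` random subsets of size `subset_size` from the expression
#' table, sorts each, and averages the order statistics position-wise; the
#' result is a smooth reference sample of length `subset_size` whose shape
#' converges to the population quantiles.
#'
#' @param table data.frame with `gene_id` and `tpm`.
#' @param subset_size size of each random subset (< table size).
#' @param reps number of random subsets (default 10000).
#' @param seed RNG seed.
#' @return sorted numeric vector of length `subset_size`.
#' @export
build_random_reference <- function(table, subset_size, reps = 10000L, seed = 42L) {
  tpm <- table$tpm
  if (subset_size >= length(tpm)) stop("subset_size must be smaller than the table")
  set.seed(seed)
  acc <- numeric(subset_size)
  for (i in seq_len(reps))
    acc <- acc + sort(tpm[sample.int(length(tpm), subset_size)])
  acc / reps
}

#' Select silent genes from an expression table
#'
#' @param table data.frame with `gene_id` and `tpm`.
#' @param gene_list gene ids to filter (ids absent from the table are
#'   excluded with a warning).
#' @param lo,hi inclusive TPM bounds defining "silent" (default 0 to 0.01).
#' @return gene ids of `gene_list` with `lo <= tpm <= hi`.
#' @export
select_silent_genes <- function(table, gene_list, lo = 0, hi = 0.01) {
  if (lo > hi) stop("lo must be <= hi")
  idx <- match(gene_list, table$gene_id)
  if (any(is.na(idx))) {
    warning(sum(is.na(idx)), " gene(s) absent from the expression table; excluded")
    gene_list <- gene_list[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  tpm <- table$tpm[idx]
  gene_list[tpm >= lo & tpm <= hi]
}
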