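#' Monte Carlo exact test of Hardy-Weinberg equilibrium at one locus
#'
#' Exact-style Monte Carlo test of Hardy-Weinberg proportions within a group.
#' The test statistic is the conditional probability of the observed genotype
#' array given the allele counts; only the terms that vary under re-pairing are
#' kept, so the statistic used is `h * log(2) - sum(lfactorial(genotype
#' counts))` with `h` the number of heterozygotes. Each permutation randomly
#' re-pairs the locus's gene copies into diploid genotypes, and
#' `p = (1 + #[permuted arrays at most as probable as observed]) / (n_perm + 1)`,
#' so p can never be exactly zero.
#'
#' @param x A [genotype_dataset()].
#' @param group Group label.
#' @param locus Locus name.
#' @param n_perm Number of Monte Carlo re-pairings (>= 1).
#' @param seed Optional integer seed.
#' @return List with `p_value`, `n_het`, `n`, and `monomorphic` (`TRUE` when
#'   only one allele segregates, in which case `p_value` is 1 by convention,
#'   not an error).
#' @export
hwe_test <- function(x, group, locus, n_perm = 2000, seed = NULL) {
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  l <- match(locus, x$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  sel <- x$ind$group == group & !is.na(x$a1[, l])
  g1 <- x$a1[sel, l]; g2 <- x$a2[sel, l]
  n <- length(g1)
  if (n < 2) stop("need at least 2 non-missing genotypes for an HWE test")
  copies <- c(g1, g2)
  if (length(unique(copies)) < 2)
    return(list(p_value = 1, n_het = 0L, n = n, monomorphic = TRUE))
  array_stat <- function(u, v) {
    tab <- table(paste(pmin(u, v), pmax(u, v)))
    sum(u != v) * log(2) - sum(lfactorial(tab))
  }
  t_obs <- array_stat(g1, g2)
  odd <- seq(1, 2 * n, by = 2)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(copies)
    if (array_stat(perm[odd], perm[odd + 1L]) <= t_obs + 1e-9) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (n_perm + 1), n_het = sum(g1 != g2), n = n,
       monomorphic = FALSE)
}

#' HWE tests for every locus in every group
#'
#' Convenience wrapper running [hwe_test()] across a table of groups and loci,
#' with a Bonferroni flag treating the whole table as one family of
#' simultaneous tests.
#'
#' @param x A [genotype_dataset()].
#' @param groups Group labels (default all).
#' @param n_perm Permutations per test.
#' @param seed Optional integer seed.
#' @param alpha Family-wise level for the Bonferroni flag.
#' @return Data frame with `group`, `locus`, `p_value`, `monomorphic`,
#'   `significant` (Bonferroni-corrected).
#' @export
hwe_table <- function(x, groups = NULL, n_perm = 2000, seed = NULL,
                      alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(groups)) groups <- dataset_groups(x)
  grid <- expand.grid(group = groups, locus = x$loci,
                      stringsAsFactors = FALSE)
  res <- mapply(function(g, l) {
    r <- hwe_test(x, g, l, n_perm = n_perm)
    c(r$p_value, r$monomorphic)
  }, grid$group, grid$locus)
  grid$p_value <- res[1, ]
  grid$monomorphic <- as.logical(res[2, ])
  grid$significant <- bonferroni_significant(grid$p_value, alpha)
  grid
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Tests association between the genotypes at two loci within one group using
#' a G (log-likelihood ratio) statistic on the two-locus genotype contingency
#' table. Significance comes from shuffling one locus's genotypes across
#' individuals, which preserves both single-locus genotype distributions while
#' breaking any between-locus association. Either locus being monomorphic
#' among the shared individuals gives p = 1 (no association is possible).
#'
#' @param x A [genotype_dataset()].
#' @param group Group label.
#' @param locusA,locusB Locus names.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List with `p_value`, `g_stat`, `n` (shared non-missing
#'   individuals).
#' @export
ld_test <- function(x, group, locusA, locusB, n_perm = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  la <- match(locusA, x$loci); lb <- match(locusB, x$loci)
  if (is.na(la) || is.na(lb)) stop("unknown locus name")
  sel <- x$ind$group == group & !is.na(x$a1[, la]) & !is.na(x$a1[, lb])
  n <- sum(sel)
  if (n < 2) stop("need at least 2 individuals genotyped at both loci")
  ga <- paste(x$a1[sel, la], x$a2[sel, la])
  gb <- paste(x$a1[sel, lb], x$a2[sel, lb])
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2)
    return(list(p_value = 1, g_stat = 0, n = n))
  g_stat <- function(u, v) {
    tab <- table(u, v)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- tab[tab > 0]
    2 * sum(o * log(o / e[tab > 0]))
  }
  t_obs <- g_stat(ga, gb)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (g_stat(ga, sample(gb)) >= t_obs - 1e-9) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (n_perm + 1), g_stat = t_obs, n = n)
}
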