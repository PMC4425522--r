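#' Monte Carlo exact test of allele-frequency differentiation
#'
#' Per-locus exact-style test of population differentiation on the group x
#' allele contingency table of allele counts. The null distribution is all
#' tables with the observed margins (multivariate hypergeometric); the
#' p-value is the probability of tables as probable as or less probable than
#' the observed one. It is estimated by direct Monte Carlo resampling:
#' each replicate randomly re-partitions the pooled gene copies into the two
#' groups (preserving margins) and compares the table's log-probability
#' `-(sum(lfactorial(cells)))` (margin terms are constant) with the observed
#' one, with the add-one rule so p is never 0.
#'
#' Per-locus p-values are combined across loci by Fisher's method:
#' `X = -2 * sum(log(p_l))` compared against a chi-square with `2L` degrees of
#' freedom. A locus monomorphic across both groups has `p_l = 1`.
#'
#' A `n_dememorization` argument is accepted for interface parity with
#' Markov-chain implementations of this test; the direct sampler draws
#' independent tables, so the burn-in is a no-op.
#'
#' @param x A [genotype_dataset()].
#' @param groupA,groupB Group labels.
#' @param n_perm Monte Carlo tables per locus.
#' @param n_dememorization Accepted and ignored (direct sampling needs no
#'   burn-in).
#' @param seed Optional integer seed.
#' @return List with `per_locus` (data frame `locus`, `p_value`,
#'   `monomorphic`), `chi_sq` (Fisher combination statistic), `df`, and
#'   `p_combined`.
#' @export
exact_differentiation <- function(x, groupA, groupB, n_perm = 2000,
                                  n_dememorization = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  selA <- x$ind$group == groupA; selB <- x$ind$group == groupB
  if (!any(selA) || !any(selB)) stop("empty or unknown group")
  L <- length(x$loci)
  p_l <- rep(NA_real_, L); mono <- logical(L)
  for (l in seq_len(L)) {
    ca <- c(x$a1[selA, l], x$a2[selA, l]); ca <- ca[!is.na(ca)]
    cb <- c(x$a1[selB, l], x$a2[selB, l]); cb <- cb[!is.na(cb)]
    alleles <- sort(unique(c(ca, cb)))
    if (length(alleles) < 2 || length(ca) == 0 || length(cb) == 0) {
      p_l[l] <- 1; mono[l] <- TRUE
      next
    }
    obs <- rbind(tabulate(match(ca, alleles), length(alleles)),
                 tabulate(match(cb, alleles), length(alleles)))
    t_obs <- -sum(lfactorial(obs))
    pool <- rep(seq_along(alleles), colSums(obs))
    nA <- length(ca)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      ia <- tabulate(sample(pool, nA), length(alleles))
      tab <- rbind(ia, colSums(obs) - ia)
      if (-sum(lfactorial(tab)) <= t_obs + 1e-9) hits <- hits + 1L
    }
    p_l[l] <- (1 + hits) / (n_perm + 1)
  }
  chi_sq <- -2 * sum(log(p_l))
  df <- 2L * L
  list(per_locus = data.frame(locus = x$loci, p_value = p_l,
                              monomorphic = mono),
       chi_sq = chi_sq, df = df,
       p_combined = stats::pchisq(chi_sq, df, lower.tail = FALSE))
}
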