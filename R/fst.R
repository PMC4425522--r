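#' Weir-Cockerham F_ST (theta) with permutation significance
#'
#' Estimates F_ST between (or among) groups with the Weir & Cockerham (1984)
#' variance-components estimator theta. For every locus and allele the three
#' components are computed with the unequal-sample-size formulas: `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals), then summed over alleles to per-locus components. The
#' multilocus estimate is the components ratio
#' `sum(a) / sum(a + b + c)` over loci, the standard weighting. Negative
#' per-locus theta values are reported as computed -- truncating them at zero
#' would bias the multilocus estimate.
#'
#' Loci where `a + b + c = 0` (monomorphic across the groups) carry no
#' information about differentiation; they are excluded from the sums and
#' listed in the result.
#'
#' Significance is assessed by permuting individuals between the groups
#' (keeping group sizes) and recomputing the multilocus theta;
#' `p = (1 + #[theta_perm >= theta_obs]) / (n_perm + 1)`.
#'
#' @param x A [genotype_dataset()].
#' @param groups Character vector of two or more group labels.
#' @param n_perm Number of label permutations for the p-value (0 = no test).
#' @param seed Optional integer seed.
#' @return Object of class `fst_result`: list with `per_locus` (data frame of
#'   per-locus `a`, `b`, `c`, `theta`), `theta` (multilocus), `excluded_loci`,
#'   `p_value` (`NA` when `n_perm = 0`), `n_perm`.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics for
#'   the analysis of population structure. Evolution 38:1358-1370.
#' @export
weir_cockerham_fst <- function(x, groups, n_perm = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(groups) < 2) stop("need at least two groups")
  sel <- x$ind$group %in% groups
  if (!all(groups %in% x$ind$group)) stop("empty or unknown group")
  a1 <- x$a1[sel, , drop = FALSE]; a2 <- x$a2[sel, , drop = FALSE]
  pop <- factor(x$ind$group[sel], levels = groups)

  comp <- wc_components(a1, a2, pop)
  tot <- comp$a + comp$b + comp$c
  keep <- is.finite(tot) & tot > 0
  theta <- sum(comp$a[keep]) / sum(tot[keep])
  per_locus <- data.frame(locus = x$loci, a = comp$a, b = comp$b, c = comp$c,
                          theta = ifelse(keep, comp$a / tot, NA_real_))
  p_value <- NA_real_
  if (n_perm > 0) {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pp <- sample(pop)
      cm <- wc_components(a1, a2, pp)
      tt <- cm$a + cm$b + cm$c
      kk <- is.finite(tt) & tt > 0
      if (sum(cm$a[kk]) / sum(tt[kk]) >= theta - 1e-12) hits <- hits + 1L
    }
    p_value <- (1 + hits) / (n_perm + 1)
  }
  structure(list(per_locus = per_locus, theta = theta,
                 excluded_loci = x$loci[!keep], p_value = p_value,
                 n_perm = n_perm),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham multilocus theta = %.4f", x$theta))
  if (!is.na(x$p_value))
    cat(sprintf("  (permutation p = %.4g, %d permutations)", x$p_value,
                x$n_perm))
  cat("\n")
  if (length(x$excluded_loci))
    cat("  monomorphic loci excluded:", paste(x$excluded_loci, collapse = ", "),
        "\n")
  invisible(x)
}

# Per-locus Weir-Cockerham variance components a, b, c (summed over alleles).
# Populations with no scored individuals at a locus drop out of that locus;
# a locus informative in fewer than 2 populations, or with mean sample size
# <= 1, yields NA components.
wc_components <- function(a1, a2, pop) {
  L <- ncol(a1)
  a_l <- b_l <- c_l <- rep(NA_real_, L)
  lev <- levels(pop)
  for (l in seq_len(L)) {
    ok <- !is.na(a1[, l])
    if (!any(ok)) next
    p_i <- pop[ok]
    g1 <- a1[ok, l]; g2 <- a2[ok, l]
    n_i <- tabulate(p_i, nbins = length(lev))
    use <- n_i > 0
    if (sum(use) < 2) next
    r <- sum(use)
    n_i <- n_i[use]
    nbar <- mean(n_i)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(c(g1, g2)))
    if (length(alleles) < 2) { a_l[l] <- 0; b_l[l] <- 0; c_l[l] <- 0; next }
    # count per pop x allele, and per pop x allele heterozygote carriers
    pi_idx <- as.integer(factor(as.integer(p_i), levels = which(use)))
    cnt <- matrix(0, sum(use), length(alleles))
    hets <- matrix(0, sum(use), length(alleles))
    i1 <- match(g1, alleles); i2 <- match(g2, alleles)
    for (j in seq_along(g1)) {
      cnt[pi_idx[j], i1[j]] <- cnt[pi_idx[j], i1[j]] + 1
      cnt[pi_idx[j], i2[j]] <- cnt[pi_idx[j], i2[j]] + 1
      if (i1[j] != i2[j]) {
        hets[pi_idx[j], i1[j]] <- hets[pi_idx[j], i1[j]] + 1
        hets[pi_idx[j], i2[j]] <- hets[pi_idx[j], i2[j]] + 1
      }
    }
    p_ia <- cnt / (2 * n_i)          # rows recycle n_i
    h_ia <- hets / n_i
    pbar <- colSums(n_i * p_ia) / (r * nbar)
    s2 <- colSums(n_i * (p_ia - rep(pbar, each = nrow(p_ia)))^2) /
      ((r - 1) * nbar)
    hbar <- colSums(n_i * h_ia) / (r * nbar)
    a_a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b_a <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    c_a <- hbar / 2
    a_l[l] <- sum(a_a); b_l[l] <- sum(b_a); c_l[l] <- sum(c_a)
  }
  list(a = a_l, b = b_l, c = c_l)
}
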