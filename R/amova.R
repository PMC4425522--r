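#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Three-level AMOVA partitioning genetic variance among years (temporal),
#' among plume groups nested within years (spatial), and within plume groups,
#' computed on gene copies with the allele-identity distance (0 if two copies
#' carry the same allele code, 1 otherwise, summed over loci). With this
#' distance the analysis behaves like conventional F_ST partitioning rather
#' than a stepwise-mutation R_ST.
#'
#' Sums of squares are computed per locus from allele counts (using the
#' identity that the sum of pairwise mismatch distances within a set of `n`
#' copies with counts `c_a` is `(n^2 - sum(c_a^2)) / 2`, so `SS = n/2 * (1 -
#' sum(p_a^2))`), summed over loci, and the three variance components are
#' solved from the expected-mean-square equations with unequal-sample-size
#' coefficients accumulated per locus (so missing genotypes shrink a locus's
#' copy counts without dropping individuals).
#'
#' Negative variance components are reported as computed, never truncated:
#' truncation would bias the percent-variation partition, which always sums to
#' 100.
#'
#' Permutation p-values use the standard scheme per level: within-group
#' variance (Phi_ST) by permuting individuals among all plume groups;
#' among-plumes-within-years (Phi_SC) by permuting individuals among plume
#' groups within the same year; among-years (Phi_CT) by permuting whole plume
#' groups among years. Individuals are permuted as whole diploid units.
#'
#' @param x A [genotype_dataset()].
#' @param years Per-individual year labels (anything coercible to factor).
#' @param plumes Per-individual plume labels; the populations of the design
#'   are the year x plume combinations.
#' @param n_perm Number of permutations per level (0 = no tests).
#' @param seed Optional integer seed.
#' @return Object of class `amova_result`: data frame with one row per level
#'   (`among_years`, `among_plumes_within_years`, `within_plumes`) and columns
#'   `df`, `SS`, `sigma2`, `percent`, `phi`, `p_value`, plus attribute
#'   `phi_statistics`.
#' @references Excoffier, L., Smouse, P.E. & Quattro, J.M. (1992) Analysis of
#'   molecular variance inferred from metric distances among DNA haplotypes.
#'   Genetics 131:479-491.
#' @export
amova <- function(x, years, plumes, n_perm = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_individuals(x)
  years <- rep_len(as.character(years), n)
  plumes <- rep_len(as.character(plumes), n)
  if (length(unique(years)) < 2) stop("zero degrees of freedom at level 'among_years'")
  pops <- interaction(years, plumes, drop = TRUE, sep = "/")
  obs <- amova_fit(x$a1, x$a2, years, as.character(pops))

  p_vals <- rep(NA_real_, 3)
  if (n_perm > 0) {
    pop_chr <- as.character(pops)
    # within (Phi_ST): individuals among all populations
    hits_st <- 0L
    # among plumes within years (Phi_SC): individuals among pops within year
    hits_sc <- 0L
    # among years (Phi_CT): whole populations among years
    hits_ct <- 0L
    pop_year <- tapply(years, pop_chr, function(v) v[1])
    for (b in seq_len(n_perm)) {
      f1 <- amova_fit(x$a1, x$a2, years, sample(pop_chr))
      if (isTRUE(f1$phi[["phi_st"]] >= obs$phi[["phi_st"]] - 1e-12))
        hits_st <- hits_st + 1L
      perm_pop <- pop_chr
      for (y in unique(years)) {
        iy <- which(years == y)
        perm_pop[iy] <- sample(pop_chr[iy])
      }
      f2 <- amova_fit(x$a1, x$a2, years, perm_pop)
      if (isTRUE(f2$phi[["phi_sc"]] >= obs$phi[["phi_sc"]] - 1e-12))
        hits_sc <- hits_sc + 1L
      perm_year_of_pop <- sample(unname(pop_year))
      names(perm_year_of_pop) <- names(pop_year)
      f3 <- amova_fit(x$a1, x$a2, unname(perm_year_of_pop[pop_chr]), pop_chr)
      if (isTRUE(f3$phi[["phi_ct"]] >= obs$phi[["phi_ct"]] - 1e-12))
        hits_ct <- hits_ct + 1L
    }
    p_vals <- (1 + c(hits_ct, hits_sc, hits_st)) / (n_perm + 1)
  }

  out <- data.frame(
    level = c("among_years", "among_plumes_within_years", "within_plumes"),
    df = obs$df, SS = obs$SS, sigma2 = obs$sigma2,
    percent = 100 * obs$sigma2 / sum(obs$sigma2),
    phi = unname(obs$phi), p_value = p_vals)
  attr(out, "phi_statistics") <- obs$phi
  class(out) <- c("amova_result", class(out))
  out
}

# Core three-level AMOVA solve. `years` and `pops` are per-individual
# character labels; pops must nest within years.
amova_fit <- function(a1, a2, years, pops) {
  L <- ncol(a1)
  pop_lev <- unique(pops)
  year_of_pop <- vapply(pop_lev, function(p) years[match(p, pops)], "")
  year_lev <- unique(years)
  G <- length(year_lev); P <- length(pop_lev)
  if (P <= G) stop("zero degrees of freedom at level 'among_plumes_within_years'")

  ss_ag <- ss_ap <- ss_wp <- 0
  df_ag <- df_ap <- df_wp <- 0
  k_b_ap <- k_b_ag <- k_a_ag <- 0
  ssq <- function(codes) {         # SS within a pooled set of gene copies
    n <- length(codes)
    if (n == 0) return(c(ss = 0, n = 0))
    cnt <- table(codes)
    c(ss = (n^2 - sum(cnt^2)) / (2 * n), n = n)
  }
  for (l in seq_len(L)) {
    ok <- !is.na(a1[, l])
    if (!any(ok)) next
    codes <- c(a1[ok, l], a2[ok, l])
    cp <- rep(pops[ok], 2)
    cy <- rep(years[ok], 2)
    per_pop <- vapply(pop_lev, function(p) ssq(codes[cp == p]), c(ss = 0, n = 0))
    per_year <- vapply(year_lev, function(y) ssq(codes[cy == y]), c(ss = 0, n = 0))
    tot <- ssq(codes)
    N <- tot["n"]
    n_p <- per_pop["n", ]; n_g <- per_year["n", ]
    used_p <- sum(n_p > 0); used_g <- sum(n_g > 0)
    if (used_p < 2 || used_g < 1) next
    ss_wp <- ss_wp + sum(per_pop["ss", ])
    ss_ap <- ss_ap + sum(per_year["ss", ]) - sum(per_pop["ss", ])
    ss_ag <- ss_ag + tot["ss"] - sum(per_year["ss", ])
    df_wp <- df_wp + (N - used_p)
    df_ap <- df_ap + (used_p - used_g)
    df_ag <- df_ag + (used_g - 1)
    sum_np2_over_ng <- sum(vapply(year_lev, function(y) {
      ip <- year_of_pop == y & n_p > 0
      if (!any(ip)) return(0)
      sum(n_p[ip]^2) / sum(n_p[ip])
    }, 0))
    k_b_ap <- k_b_ap + (N - sum_np2_over_ng)
    k_b_ag <- k_b_ag + (sum_np2_over_ng - sum(n_p^2) / N)
    k_a_ag <- k_a_ag + (N - sum(n_g^2) / N)
  }
  if (df_wp <= 0) stop("zero degrees of freedom at level 'within_plumes'")
  if (df_ap <= 0) stop("zero degrees of freedom at level 'among_plumes_within_years'")
  if (df_ag <= 0) stop("zero degrees of freedom at level 'among_years'")
  ss_ag <- unname(ss_ag); ss_ap <- unname(ss_ap); ss_wp <- unname(ss_wp)
  df_ag <- unname(df_ag); df_ap <- unname(df_ap); df_wp <- unname(df_wp)
  k_b_ap <- unname(k_b_ap); k_b_ag <- unname(k_b_ag); k_a_ag <- unname(k_a_ag)
  sig_c <- ss_wp / df_wp
  sig_b <- (ss_ap - sig_c * df_ap) / k_b_ap
  sig_a <- (ss_ag - sig_c * df_ag - sig_b * k_b_ag) / k_a_ag
  tot_var <- sig_a + sig_b + sig_c
  phi <- c(phi_ct = sig_a / tot_var,
           phi_sc = sig_b / (sig_b + sig_c),
           phi_st = (sig_a + sig_b) / tot_var)
  list(df = unname(c(df_ag, df_ap, df_wp)),
       SS = unname(c(ss_ag, ss_ap, ss_wp)),
       sigma2 = unname(c(sig_a, sig_b, sig_c)), phi = phi)
}
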