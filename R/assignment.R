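#' Configuration for genotype assignment
#'
#' Collects the tunable parameters of migrant screening, exclusion testing and
#' juvenile assignment. Thresholds follow the two-source logic: with
#' probabilities normalized over two candidate groups, any threshold above 0.5
#' can be satisfied by at most one group.
#'
#' Threshold operators are applied verbatim: an individual is a migrant when
#' its self-assignment probability is strictly `<` `migrant_threshold`, is
#' assigned when its normalized probability is `>=` `assign_threshold`, and a
#' candidate source is rejected when the exclusion p-value is strictly `<`
#' `exclusion_alpha`.
#'
#' @param migrant_threshold Self-assignment probability below which a
#'   reference individual is flagged as a first-generation migrant
#'   (default 0.60).
#' @param assign_threshold Normalized assignment probability at or above which
#'   a juvenile is assigned to a source (default 0.70).
#' @param exclusion_alpha Exclusion p-value below which a candidate source is
#'   rejected; a juvenile rejected by every candidate is excluded
#'   (default 0.10).
#' @param n_simulated Number of simulated genotypes in the exclusion test
#'   (default 10000).
#' @param rare_allele_floor Frequency substituted for alleles absent from a
#'   reference group in the frequency-method likelihood (default 0.01).
#' @param min_loci Minimum number of scored loci for an individual to be
#'   usable (default 6): likelihoods over very few loci are uninformative.
#' @param screen_method Likelihood used for migrant screening, `"bayesian"`
#'   (default) or `"frequency"`.
#' @param assign_method Likelihood used for the rank-based assignment step,
#'   `"frequency"` (default) or `"bayesian"`.
#' @param exclusion_method Likelihood used inside the exclusion test,
#'   `"bayesian"` (default) or `"frequency"`.
#' @param seed Optional integer seed consumed by the stochastic steps.
#' @return List of class `assignment_config`.
#' @export
assignment_config <- function(migrant_threshold = 0.60,
                              assign_threshold = 0.70,
                              exclusion_alpha = 0.10,
                              n_simulated = 10000,
                              rare_allele_floor = 0.01,
                              min_loci = 6,
                              screen_method = "bayesian",
                              assign_method = "frequency",
                              exclusion_method = "bayesian",
                              seed = NULL) {
  if (migrant_threshold <= 0.5 || migrant_threshold > 1)
    stop("'migrant_threshold' must lie in (0.5, 1]")
  if (assign_threshold <= 0.5 || assign_threshold > 1)
    stop("'assign_threshold' must lie in (0.5, 1]")
  if (rare_allele_floor <= 0 || rare_allele_floor >= 1)
    stop("'rare_allele_floor' must lie in (0, 1)")
  if (n_simulated < 100) stop("'n_simulated' must be >= 100")
  structure(list(migrant_threshold = migrant_threshold,
                 assign_threshold = assign_threshold,
                 exclusion_alpha = exclusion_alpha,
                 n_simulated = as.integer(n_simulated),
                 rare_allele_floor = rare_allele_floor,
                 min_loci = as.integer(min_loci),
                 screen_method = match.arg(screen_method,
                                           c("bayesian", "frequency")),
                 assign_method = match.arg(assign_method,
                                           c("frequency", "bayesian")),
                 exclusion_method = match.arg(exclusion_method,
                                              c("bayesian", "frequency")),
                 seed = seed),
            class = "assignment_config")
}

#' Multilocus genotype log-likelihood under a reference group
#'
#' Computes, for a batch of individuals, the log-likelihood of each multilocus
#' genotype under one reference group, with either the Bayesian
#' (Rannala-Mountain) criterion or the classical frequency method.
#'
#' Bayesian criterion, per locus with reference allele counts `n_a`, total
#' gene copies `n`, and `k` alleles in the pooled allele space:
#' homozygote *aa* has probability
#' `(n_a + 1/k) (n_a + 1 + 1/k) / ((n + 1)(n + 2))` and heterozygote *ab*
#' `2 (n_a + 1/k)(n_b + 1/k) / ((n + 1)(n + 2))`; with an empty reference this
#' reduces to the pure `1/k` prior. Frequency method: the Hardy-Weinberg
#' genotype probability `p^2` or `2 p q` from observed reference frequencies,
#' with any zero frequency replaced by `floor` before forming the term (no
#' renormalization). Missing loci are skipped and do not count towards
#' `n_loci_used`.
#'
#' With `loo = TRUE` the individuals are assumed to be members of the
#' reference group and their own two alleles are removed from the counts
#' before the term is formed (leave-one-out), so self-assignment is never
#' inflated by an individual's own contribution to the reference.
#'
#' @param a1,a2 Allele-code matrices (individuals x loci) aligned with
#'   `ft$loci`.
#' @param ft An [allele_freqs()] table.
#' @param group Reference group label in `ft`.
#' @param method `"bayesian"` or `"frequency"`.
#' @param floor Rare-allele frequency floor for the frequency method.
#' @param k Integer vector of pooled allele counts per locus (default:
#'   [pooled_allele_counts()] of `ft`).
#' @param loo Leave the individual's own alleles out of the reference counts.
#' @return List with `loglik` (numeric vector) and `n_loci_used` (integer
#'   vector).
#' @references Rannala, B. & Mountain, J.L. (1997) Detecting immigration by
#'   using multilocus genotypes. PNAS 94:9197-9201.
#' @export
genotype_loglik <- function(a1, a2, ft, group,
                            method = c("bayesian", "frequency"),
                            floor = 0.01, k = NULL, loo = FALSE) {
  method <- match.arg(method)
  cnts <- ft$counts[[group]]
  if (is.null(cnts)) stop("group not in frequency table: ", group)
  L <- length(ft$loci)
  n <- nrow(a1)
  if (is.null(k)) k <- pooled_allele_counts(ft)
  ll <- numeric(n); used <- integer(n)
  for (l in seq_len(L)) {
    x1 <- a1[, l]; x2 <- a2[, l]
    ok <- which(!is.na(x1))
    if (!length(ok)) next
    codes <- ft$alleles[[l]]; cnt <- cnts[[l]]; ntot <- sum(cnt)
    i1 <- match(x1[ok], codes); i2 <- match(x2[ok], codes)
    na_ <- ifelse(is.na(i1), 0, cnt[i1])
    nb_ <- ifelse(is.na(i2), 0, cnt[i2])
    hom <- x1[ok] == x2[ok]
    neff <- rep(ntot, length(ok))
    if (loo) {
      na_ <- na_ - ifelse(hom, 2, 1)
      nb_ <- nb_ - ifelse(hom, 2, 1)
      neff <- neff - 2
      if (any(na_ < 0) || any(nb_ < 0) || any(neff < 0))
        stop("leave-one-out produced negative counts; individuals must belong to the reference group")
    }
    if (method == "bayesian") {
      kk <- 1 / k[l]
      term <- ifelse(hom,
                     log(na_ + kk) + log(na_ + 1 + kk),
                     log(2) + log(na_ + kk) + log(nb_ + kk)) -
        log(neff + 1) - log(neff + 2)
    } else {
      pa <- ifelse(neff > 0, na_ / neff, 0)
      pb <- ifelse(neff > 0, nb_ / neff, 0)
      pa[pa <= 0] <- floor
      pb[pb <= 0] <- floor
      term <- ifelse(hom, 2 * log(pa), log(2) + log(pa) + log(pb))
    }
    ll[ok] <- ll[ok] + term
    used[ok] <- used[ok] + 1L
  }
  list(loglik = ll, n_loci_used = used)
}

# Row-wise normalized probabilities from a matrix of log-likelihoods,
# computed stably through log-sum-exp so 12-locus products never underflow.
normalize_loglik <- function(ll_mat) {
  m <- apply(ll_mat, 1, max)
  e <- exp(ll_mat - m)
  e / rowSums(e)
}

#' Leave-one-out self-assignment and migrant screening
#'
#' For every individual of the reference groups, computes its likelihood to
#' each candidate group -- removing its own alleles from its home group's
#' counts first -- normalizes across groups in log space, and flags the
#' individual as a putative first-generation migrant when the probability of
#' assignment to its own collection group falls strictly below
#' `config$migrant_threshold`. Individuals scored at fewer than
#' `config$min_loci` loci are marked unusable rather than screened.
#'
#' A reference group of size 1 empties under leave-one-out; the Bayesian
#' likelihood then falls back to its `1/k` prior and the frequency method to
#' all-floor frequencies, so the case is handled, not an error.
#'
#' @param x A [genotype_dataset()] containing the reference groups.
#' @param reference_groups Character vector of group labels to screen
#'   (default: all groups in `x`).
#' @param config An [assignment_config()].
#' @return Data frame with `id`, `group`, one `ll_<group>` column per
#'   candidate, `prob_home`, `n_loci_used`, `usable`, `migrant`.
#' @export
self_assign <- function(x, reference_groups = NULL, config = assignment_config()) {
  if (is.null(reference_groups)) reference_groups <- dataset_groups(x)
  if (!is.null(config$seed)) set.seed(config$seed)
  sel <- x$ind$group %in% reference_groups
  refs <- if (all(sel)) x else subset_individuals(x, which(sel))
  ft <- allele_freqs(refs, groups = reference_groups)
  k <- pooled_allele_counts(ft)
  nr <- n_individuals(refs)
  ll <- matrix(NA_real_, nr, length(reference_groups),
               dimnames = list(NULL, reference_groups))
  used <- integer(nr)
  for (g in reference_groups) {
    home <- refs$ind$group == g
    for (h in reference_groups) {
      r <- genotype_loglik(refs$a1[home, , drop = FALSE],
                           refs$a2[home, , drop = FALSE], ft, h,
                           method = config$screen_method,
                           floor = config$rare_allele_floor, k = k,
                           loo = identical(g, h))
      ll[home, h] <- r$loglik
      if (identical(g, h)) used[home] <- r$n_loci_used
    }
  }
  prob <- normalize_loglik(ll)
  home_idx <- match(refs$ind$group, reference_groups)
  prob_home <- prob[cbind(seq_len(nr), home_idx)]
  usable <- used >= config$min_loci
  out <- data.frame(id = refs$ind$id, group = refs$ind$group,
                    stringsAsFactors = FALSE)
  for (g in reference_groups) out[[paste0("ll_", g)]] <- ll[, g]
  out$prob_home <- prob_home
  out$n_loci_used <- used
  out$usable <- usable
  out$migrant <- usable & (prob_home < config$migrant_threshold)
  out
}

#' Remove flagged migrants from a reference dataset
#'
#' @param x A [genotype_dataset()].
#' @param screen Output of [self_assign()] on `x`.
#' @return `x` restricted to usable, non-migrant individuals.
#' @export
drop_migrants <- function(x, screen) {
  keep <- screen$id[screen$usable & !screen$migrant]
  subset_individuals(x, x$ind$id %in% keep)
}

#' Monte Carlo exclusion test of a candidate source population
#'
#' Simulates `n_sim` multilocus genotypes by drawing two alleles per locus
#' independently from the candidate group's reference frequencies, scores
#' every simulated genotype with the configured likelihood, and returns for
#' each query individual the proportion of simulated genotypes whose
#' likelihood is at most the individual's own (add-one smoothed:
#' `p = (1 + #[sim <= obs]) / (n_sim + 1)`). A small p means genotypes as
#' unlikely as the query's essentially never arise in the candidate
#' population, excluding it as a source. Simulated likelihoods are summed
#' over exactly the loci scored in each query individual, so missing data
#' never distort the comparison.
#'
#' @param x A [genotype_dataset()] of query individuals (or a subset).
#' @param ft Reference [allele_freqs()] table.
#' @param group Candidate group label in `ft`.
#' @param n_sim Number of simulated genotypes.
#' @param method Likelihood criterion, `"bayesian"` or `"frequency"`.
#' @param floor Rare-allele floor for the frequency method.
#' @param k Pooled allele counts per locus (default from `ft`).
#' @param seed Optional integer seed.
#' @return Numeric vector of exclusion p-values, one per query individual.
#' @references Paetkau, D., Slade, R., Burden, M. & Estoup, A. (2004)
#'   Genetic assignment methods for the direct, real-time estimation of
#'   migration rate. Molecular Ecology 13:55-65.
#' @export
exclusion_test <- function(x, ft, group, n_sim = 10000,
                           method = c("bayesian", "frequency"),
                           floor = 0.01, k = NULL, seed = NULL) {
  method <- match.arg(method)
  if (n_sim < 100) stop("'n_sim' must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(k)) k <- pooled_allele_counts(ft)
  freqs <- group_frequencies(ft, group)
  L <- length(ft$loci)
  sim1 <- matrix(NA_integer_, n_sim, L)
  sim2 <- matrix(NA_integer_, n_sim, L)
  for (l in seq_len(L)) {
    p <- freqs[[l]]
    if (sum(p) == 0) next  # locus unscored in reference: stays missing
    codes <- ft$alleles[[l]]
    sim1[, l] <- codes[sample.int(length(codes), n_sim, replace = TRUE, prob = p)]
    sim2[, l] <- codes[sample.int(length(codes), n_sim, replace = TRUE, prob = p)]
  }
  # per-locus log-likelihood contributions of simulated and query genotypes
  sim_ll <- matrix(0, n_sim, L)
  q_ll <- matrix(0, n_individuals(x), L)
  for (l in seq_len(L)) {
    sim_ll[, l] <- genotype_loglik(sim1[, l, drop = FALSE],
                                   sim2[, l, drop = FALSE],
                                   locus_slice(ft, l), group,
                                   method = method, floor = floor,
                                   k = k[l])$loglik
    q <- genotype_loglik(x$a1[, l, drop = FALSE], x$a2[, l, drop = FALSE],
                         locus_slice(ft, l), group,
                         method = method, floor = floor, k = k[l])
    q_ll[, l] <- q$loglik
  }
  usable <- !is.na(x$a1)                    # query's scored loci
  storage.mode(usable) <- "double"
  obs <- rowSums(q_ll * usable)
  sim_totals <- sim_ll %*% t(usable)        # n_sim x n_query
  p <- (1 + colSums(sweep(sim_totals, 2, obs, "<=") * 1)) / (n_sim + 1)
  unname(p)
}

# Single-locus view of an allele_freq_table (keeps group structure).
locus_slice <- function(ft, l) {
  structure(list(loci = ft$loci[l],
                 alleles = ft$alleles[l],
                 counts = lapply(ft$counts, function(cl) cl[l]),
                 n_copies = ft$n_copies[, l, drop = FALSE]),
            class = "allele_freq_table")
}

#' Two-step genotype assignment of juveniles to larval source groups
#'
#' Implements the two-step mixed-stock assignment procedure for exactly two
#' candidate sources. Step 1 (exclusion): each juvenile receives a Monte Carlo
#' [exclusion_test()] p-value against each source; a juvenile whose p-values
#' are both strictly below `config$exclusion_alpha` is `"excluded"` --
#' plausibly from an unsampled source. Step 2 (rank-based assignment): for the
#' remainder, the configured assignment likelihood (frequency method by
#' default) is normalized across the two sources; a probability at or above
#' `config$assign_threshold` assigns the juvenile to that source, anything
#' else is a `"failed"` (ambiguous) assignment. Juveniles scored at fewer than
#' `config$min_loci` loci are `"unusable"`.
#'
#' The reference dataset is expected to be migrant-filtered already (see
#' [self_assign()] and [drop_migrants()]).
#'
#' @param juveniles A [genotype_dataset()] of unknown-origin individuals.
#' @param references A [genotype_dataset()] with exactly two groups.
#' @param config An [assignment_config()].
#' @return List of class `assignment_result`: `results` (one row per juvenile:
#'   log-likelihoods, normalized probabilities, exclusion p-values, category,
#'   `n_loci_used`), `summary` (category counts), `groups`, `config`.
#' @export
assign_juveniles <- function(juveniles, references,
                             config = assignment_config()) {
  grp <- dataset_groups(references)
  if (length(grp) != 2)
    stop("the two-step procedure is defined for exactly two candidate groups, got ",
         length(grp))
  if (!identical(juveniles$loci, references$loci))
    stop("juveniles and references must share an identical ordered locus list")
  if (!is.null(config$seed)) set.seed(config$seed)
  ft <- allele_freqs(references, groups = grp,
                     extra_alleles = locus_alleles(juveniles))
  k <- pooled_allele_counts(ft)
  nj <- n_individuals(juveniles)

  excl <- sapply(grp, function(g)
    exclusion_test(juveniles, ft, g, n_sim = config$n_simulated,
                   method = config$exclusion_method,
                   floor = config$rare_allele_floor, k = k))
  excl <- matrix(excl, nrow = nj, dimnames = list(NULL, grp))

  ll <- matrix(NA_real_, nj, 2, dimnames = list(NULL, grp))
  used <- integer(nj)
  for (g in grp) {
    r <- genotype_loglik(juveniles$a1, juveniles$a2, ft, g,
                         method = config$assign_method,
                         floor = config$rare_allele_floor, k = k)
    ll[, g] <- r$loglik
    used <- r$n_loci_used
  }
  prob <- normalize_loglik(ll)

  category <- categorize_assignments(prob, excl, used, grp, config)
  res <- data.frame(id = juveniles$ind$id, stringsAsFactors = FALSE)
  for (g in grp) res[[paste0("ll_", g)]] <- ll[, g]
  for (g in grp) res[[paste0("prob_", g)]] <- prob[, g]
  for (g in grp) res[[paste0("excl_p_", g)]] <- excl[, g]
  res$category <- category
  res$n_loci_used <- used
  res$lat <- juveniles$ind$lat
  res$lon <- juveniles$ind$lon

  structure(list(results = res, summary = assignment_summary(category, grp),
                 groups = grp, config = config),
            class = "assignment_result")
}

# Applies the threshold operators to probability/exclusion matrices.
categorize_assignments <- function(prob, excl, used, grp, config) {
  nj <- nrow(prob)
  category <- rep("failed", nj)
  both_excluded <- excl[, 1] < config$exclusion_alpha &
    excl[, 2] < config$exclusion_alpha
  category[both_excluded] <- "excluded"
  for (g in grp) {
    hit <- !both_excluded & prob[, g] >= config$assign_threshold
    category[hit] <- paste0("assigned-", g)
  }
  category[used < config$min_loci] <- "unusable"
  category
}

assignment_summary <- function(category, grp) {
  lev <- c(paste0("assigned-", grp), "failed", "excluded", "unusable")
  counts <- table(factor(category, levels = lev))
  out <- as.data.frame(t(as.matrix(counts)))
  names(out) <- c(grp, "failed", "excluded", "unusable")
  out$total <- length(category)
  out
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("Two-step genotype assignment over groups:",
      paste(x$groups, collapse = " vs "), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Sensitivity of assignment outcomes to the probability threshold
#'
#' Re-applies the rank-based assignment step of [assign_juveniles()] at a
#' series of probability thresholds (exclusion p-values are computed once and
#' reused), reporting at each threshold the number assigned to each source,
#' their ratio, and the Weir-Cockerham theta between the two assigned juvenile
#' sets. As the threshold rises the acceptance regions nest, so the total
#' number assigned is non-increasing; theta between the assigned sets tends to
#' rise because only increasingly source-typical genotypes are kept.
#'
#' @param juveniles,references,config As in [assign_juveniles()].
#' @param thresholds Numeric vector of thresholds, each in (0.5, 1).
#' @return Data frame with `threshold`, `n_<group>` counts, `n_assigned`,
#'   `ratio` (first group : second group, `NA` when the second group has no
#'   assignments), and `theta_assigned` (`NA` when either set is empty).
#' @export
sensitivity_sweep <- function(juveniles, references, thresholds,
                              config = assignment_config()) {
  if (any(thresholds <= 0.5 | thresholds >= 1))
    stop("thresholds must each lie in (0.5, 1)")
  base <- assign_juveniles(juveniles, references, config)
  grp <- base$groups
  prob <- as.matrix(base$results[paste0("prob_", grp)])
  colnames(prob) <- grp
  excl <- as.matrix(base$results[paste0("excl_p_", grp)])
  colnames(excl) <- grp
  used <- base$results$n_loci_used
  out <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$assign_threshold <- th
    category <- categorize_assignments(prob, excl, used, grp, cfg)
    n1 <- sum(category == paste0("assigned-", grp[1]))
    n2 <- sum(category == paste0("assigned-", grp[2]))
    theta <- NA_real_
    if (n1 >= 2 && n2 >= 2) {
      keep <- category %in% paste0("assigned-", grp)
      asg <- subset_individuals(juveniles, which(keep))
      asg$ind$group <- sub("^assigned-", "", category[keep])
      th_fst <- weir_cockerham_fst(asg, grp, n_perm = 0)
      theta <- th_fst$theta
    }
    data.frame(threshold = th, n1 = n1, n2 = n2, n_assigned = n1 + n2,
               ratio = if (n2 > 0) n1 / n2 else NA_real_,
               theta_assigned = theta)
  })
  out <- do.call(rbind, out)
  names(out)[2:3] <- paste0("n_", grp)
  out
}
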