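# Frequency table over a fixed two-allele space with chosen counts.
make_ft <- function(countsA, countsB = NULL, codes = NULL) {
  if (is.null(codes)) codes <- seq_along(countsA)
  groups <- if (is.null(countsB)) list(R = countsA)
  else list(A = countsA, B = countsB)
  counts <- lapply(groups, function(v) {
    names(v) <- codes
    list(as.numeric(v))
  })
  structure(list(loci = "l1", alleles = list(l1 = as.integer(codes)),
                 counts = counts,
                 n_copies = matrix(vapply(groups, sum, 0), ncol = 1,
                                   dimnames = list(names(groups), "l1"))),
            class = "allele_freq_table")
}

test_that("Bayesian locus probabilities match the closed-form arithmetic", {
  ft0 <- make_ft(c(0, 0))       # empty reference, k = 2
  p_aa <- exp(genotype_loglik(matrix(1L), matrix(1L), ft0, "R")$loglik)
  p_bb <- exp(genotype_loglik(matrix(2L), matrix(2L), ft0, "R")$loglik)
  p_ab <- exp(genotype_loglik(matrix(1L), matrix(2L), ft0, "R")$loglik)
  expect_equal(p_aa, 0.375, tolerance = 1e-12)
  expect_equal(p_ab, 0.25, tolerance = 1e-12)
  # genotype space normalizes exactly
  expect_equal(p_aa + p_bb + p_ab, 1, tolerance = 1e-12)

  # reference of one aa individual (n = 2, n_a = 2), k = 2
  ft1 <- make_ft(c(2, 0))
  expect_equal(exp(genotype_loglik(matrix(1L), matrix(1L), ft1, "R")$loglik),
               2.5 * 3.5 / (3 * 4), tolerance = 1e-12)
})

test_that("frequency-method probabilities apply HWE terms and the rare-allele floor", {
  ft <- make_ft(c(5, 5))        # p = 0.5 biallelic
  p_aa <- exp(genotype_loglik(matrix(1L), matrix(1L), ft, "R",
                              method = "frequency")$loglik)
  p_ab <- exp(genotype_loglik(matrix(1L), matrix(2L), ft, "R",
                              method = "frequency")$loglik)
  expect_equal(p_aa, 0.25, tolerance = 1e-12)
  expect_equal(p_ab, 0.5, tolerance = 1e-12)

  # unseen allele takes the floor: term = 2 * 0.9 * 0.01
  ft2 <- make_ft(c(9, 1, 0), codes = c(1, 2, 3))
  p <- exp(genotype_loglik(matrix(1L), matrix(3L), ft2, "R",
                           method = "frequency", floor = 0.01)$loglik)
  expect_equal(p, 2 * 0.9 * 0.01, tolerance = 1e-12)

  # all loci missing except one matching monomorphic locus: log-likelihood 0
  ds <- make_ds(cbind("7/7", NA), c("R"))
  ftm <- allele_freqs(make_ds(cbind(c("7/7", "7/7"), c("1/2", "1/1")),
                              rep("R", 2)))
  r <- genotype_loglik(ds$a1, ds$a2, ftm, "R", method = "frequency")
  expect_equal(r$loglik, 0)
  expect_equal(r$n_loci_used, 1L)
})

test_that("normalized assignment probabilities sum to one without underflow", {
  set.seed(61)
  ds <- make_bn_pair(0.01, 60, seed = 62)
  sa <- self_assign(ds, c("A", "B"), assignment_config(min_loci = 1))
  prob_cols <- cbind(exp(sa$ll_A - pmax(sa$ll_A, sa$ll_B)),
                     exp(sa$ll_B - pmax(sa$ll_A, sa$ll_B)))
  expect_true(all(abs(rowSums(prob_cols / rowSums(prob_cols)) - 1) < 1e-12))
  expect_true(all(sa$prob_home >= 0 & sa$prob_home <= 1))
  # 12-locus log-likelihoods are far below log(.Machine$double.xmin) risk zone
  expect_true(all(is.finite(sa$ll_A) & is.finite(sa$ll_B)))
})

test_that("self-assignment is symmetric for identical references and sharp for fixed differences", {
  # two identical reference groups: every home probability 0.5, all migrants
  geno <- c("1/1", "1/2", "2/2", "1/2")
  ds <- make_ds(cbind(rep(geno, 2)), rep(c("A", "B"), each = 4))
  sa <- self_assign(ds, c("A", "B"), assignment_config(min_loci = 1))
  expect_true(all(abs(sa$prob_home - 0.5) < 0.15))
  expect_true(all(sa$migrant))

  # fixed difference: home probability ~1, no migrants
  ds2 <- make_ds(cbind(c(rep("1/1", 4), rep("2/2", 4))),
                 rep(c("A", "B"), each = 4))
  sa2 <- self_assign(ds2, c("A", "B"), assignment_config(min_loci = 1))
  expect_true(all(sa2$prob_home > 0.95))
  expect_false(any(sa2$migrant))
})

test_that("leave-one-out removes the individual's own inflation of its home likelihood", {
  # one outlier homozygote for an allele otherwise absent from its group:
  # with LOO its home likelihood must not benefit from its own two copies
  ds <- make_ds(cbind(c("3/3", rep("1/1", 5), rep("1/2", 6))),
                rep(c("A", "B"), each = 6))
  ft <- allele_freqs(ds)
  with_self <- genotype_loglik(matrix(3L), matrix(3L), ft, "A")$loglik
  loo <- genotype_loglik(ds$a1[1, , drop = FALSE], ds$a2[1, , drop = FALSE],
                         ft, "A", loo = TRUE)$loglik
  expect_lt(loo, with_self)
  # and the LOO value equals the likelihood under the group with it removed
  ds_wo <- subset_individuals(ds, 2:12)
  ft_wo <- allele_freqs(ds_wo, extra_alleles = locus_alleles(ds))
  manual <- genotype_loglik(matrix(3L), matrix(3L), ft_wo, "A")$loglik
  expect_equal(loo, manual, tolerance = 1e-12)
})

test_that("exclusion p-values behave at the degenerate and extreme ends", {
  # monomorphic reference, matching individual: p = 1
  ref <- make_ds(cbind(rep("5/5", 10)), rep("R", 10))
  ft <- allele_freqs(ref)
  q <- make_ds(cbind("5/5"), "Q")
  expect_equal(exclusion_test(q, ft, "R", n_sim = 500, seed = 1), 1)

  # individual carrying alleles absent from the reference: p at the floor
  set.seed(2)
  ref2 <- make_bn_pair(0.01, 80, seed = 3)
  ft2 <- allele_freqs(ref2, groups = "A",
                      extra_alleles = setNames(lapply(seq_len(12),
                                                      function(l) 999L),
                                               ref2$loci))
  alien <- genotype_dataset(matrix(999L, 1, 12), matrix(999L, 1, 12),
                            ref2$loci, "alien", "Q")
  p <- exclusion_test(alien, ft2, "A", n_sim = 2000, seed = 4)
  expect_lte(p, 0.01)
})

test_that("exclusion p-values are uniform for genotypes drawn from the reference itself", {
  set.seed(71)
  ds <- make_bn_pair(0.01, 100, seed = 72)
  ft <- allele_freqs(ds, groups = "A")
  fr <- group_frequencies(ft, "A")
  n_draw <- 400
  a1 <- a2 <- matrix(NA_integer_, n_draw, 12)
  for (l in 1:12) {
    a1[, l] <- sample(ft$alleles[[l]], n_draw, TRUE, prob = fr[[l]])
    a2[, l] <- sample(ft$alleles[[l]], n_draw, TRUE, prob = fr[[l]])
  }
  qs <- genotype_dataset(pmin(a1, a2), pmax(a1, a2), ds$loci,
                         sprintf("q%d", 1:n_draw), rep("Q", n_draw))
  p <- exclusion_test(qs, ft, "A", n_sim = 4000, seed = 73)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
  # type-I exclusion rate at alpha 0.10 within the binomial 95% band
  rate <- mean(p < 0.10)
  expect_lt(abs(rate - 0.10), 2 * sqrt(0.1 * 0.9 / n_draw) + 0.01)
})

test_that("two-step juvenile assignment resolves constructed and symmetric cases", {
  cfgA <- assignment_config(n_simulated = 500, min_loci = 1)
  # references with a strong frequency contrast; a juvenile matching the
  # high-frequency profile of A goes to A
  refs <- make_ds(cbind(c(rep("1/1", 8), rep("2/2", 8)),
                        c(rep("3/3", 8), rep("4/4", 8))),
                  rep(c("A", "B"), each = 8))
  juv <- make_ds(cbind("1/1", "3/3"), "JUV")
  r <- assign_juveniles(juv, refs, cfgA)
  expect_identical(r$results$category, "assigned-A")

  # identical references: probability ~0.5, assignment fails
  refs2 <- make_ds(cbind(rep(c("1/1", "1/2", "2/2", "1/2"), 2)),
                   rep(c("A", "B"), each = 4))
  juv2 <- make_ds(cbind("1/2"), "JUV")
  r2 <- assign_juveniles(juv2, refs2, cfgA)
  expect_identical(r2$results$category, "failed")
  expect_equal(r2$results$prob_A, 0.5, tolerance = 0.05)

  # more than two reference groups is a contract violation
  refs3 <- make_ds(cbind(c("1/1", "2/2", "1/2")), c("A", "B", "C"))
  expect_error(assign_juveniles(juv2, refs3, cfgA), "exactly two")
})

test_that("a 70:30 mixture at F = 0.05 is recovered within the binomial band", {
  set.seed(81)
  cfg <- sim_config(fst = 0.05, n_larvae = c(Detroit = 150, Maumee = 150),
                    n_juveniles = 100, migrant_fraction = 0, missing_rate = 0,
                    weekly_means = list(Detroit = c(70), Maumee = c(30)),
                    seed = 82)
  pops <- simulate_populations(cfg)
  ind <- simulate_individuals(pops, cfg)
  ac <- assignment_config(n_simulated = 1000)
  r <- assign_juveniles(ind$juveniles, ind$larvae, ac)
  res <- merge(r$results, ind$truth, by = "id")
  asg <- res[grepl("^assigned", res$category), ]
  # correctness against truth
  expect_gt(mean(paste0("assigned-", substr(asg$true_origin, 1, 1), "06") ==
                   asg$category), 0.9)
  # recovered Detroit fraction within the 95% binomial band around 0.70
  n_d <- sum(asg$category == "assigned-D06")
  n_tot <- nrow(asg)
  expect_lt(abs(n_d / n_tot - 0.70), 1.96 * sqrt(0.7 * 0.3 / n_tot) + 0.02)
})

test_that("sensitivity sweeps shrink and sharpen assigned sets as thresholds rise", {
  set.seed(91)
  cfg <- sim_config(fst = 0.05, n_larvae = c(Detroit = 120, Maumee = 120),
                    n_juveniles = 120, migrant_fraction = 0,
                    missing_rate = 0, seed = 92)
  pops <- simulate_populations(cfg)
  ind <- simulate_individuals(pops, cfg)
  ac <- assignment_config(n_simulated = 500)
  sw <- sensitivity_sweep(ind$juveniles, ind$larvae,
                          thresholds = c(0.55, 0.65, 0.75, 0.85, 0.95), ac)
  # nested acceptance regions: total assigned non-increasing in threshold
  expect_true(all(diff(sw$n_assigned) <= 0))
  # theta between assigned sets non-decreasing up to MC noise
  th <- sw$theta_assigned[!is.na(sw$theta_assigned)]
  if (length(th) > 1) expect_true(all(diff(th) > -0.01))

  # identical references: ratio ~1 at every threshold
  geno <- rep(c("1/1", "1/2", "2/2", "1/2"), 5)
  refs <- make_ds(cbind(geno, rev(geno)), rep(c("A", "B"), 10))
  juvs <- make_ds(cbind(rep("1/2", 40), rep("1/2", 40)), rep("JUV", 40))
  sw2 <- sensitivity_sweep(juvs, refs, c(0.55, 0.7),
                           assignment_config(n_simulated = 500, min_loci = 1,
                                             exclusion_alpha = 0))
  expect_true(all(is.na(sw2$ratio) | abs(log(sw2$ratio)) < log(3)))
  expect_error(sensitivity_sweep(juvs, refs, 0.4), "0.5")
})

test_that("with exclusion disabled and a bare threshold every usable juvenile is assigned", {
  set.seed(95)
  cfg <- sim_config(fst = 0.05, n_larvae = c(Detroit = 60, Maumee = 60),
                    n_juveniles = 40, migrant_fraction = 0, missing_rate = 0,
                    seed = 96)
  pops <- simulate_populations(cfg)
  ind <- simulate_individuals(pops, cfg)
  ac <- assignment_config(n_simulated = 500, exclusion_alpha = 0,
                          assign_threshold = 0.500001)
  r <- assign_juveniles(ind$juveniles, ind$larvae, ac)
  expect_equal(sum(r$results$category == "failed"), 0)
  expect_equal(r$summary$excluded, 0)
})

test_that("self-assignment accuracy rises with divergence", {
  accs <- vapply(c(0.0, 0.005, 0.01, 0.05, 0.1), function(f) {
    mean(vapply(1:4, function(rep) {
      ds <- make_bn_pair(f, 120, seed = 1000 + round(1e4 * f) + rep)
      sa <- self_assign(ds, c("A", "B"), assignment_config(min_loci = 1))
      mean(sa$prob_home > 0.5)
    }, 0))
  }, 0)
  expect_true(all(diff(accs) > -0.02))
  expect_gt(accs[5], accs[1])
})
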