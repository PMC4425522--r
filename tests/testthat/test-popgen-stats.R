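# Exhaustive enumeration of perfect matchings of gene copies; independent
# oracle for the Monte Carlo HWE test on tiny inputs.
enumerate_hwe_p <- function(copies) {
  match_all <- function(items) {
    if (length(items) == 0) return(list(integer(0)))
    rest <- items[-1]
    out <- list()
    for (j in seq_along(rest)) {
      for (m in match_all(rest[-j])) {
        out[[length(out) + 1]] <- c(items[1], rest[j], m)
      }
    }
    out
  }
  stat <- function(u, v) {
    sum(u != v) * log(2) - sum(lfactorial(table(paste(pmin(u, v), pmax(u, v)))))
  }
  ms <- match_all(seq_along(copies))
  vapply(ms, function(m) {
    o <- seq(1, length(copies), by = 2)
    stat(copies[m[o]], copies[m[o + 1]])
  }, 0)
}

test_that("HWE exact test handles monomorphic loci and matches enumeration", {
  mono <- make_ds(cbind(rep("1/1", 4)), rep("A", 4))
  r <- hwe_test(mono, "A", "loc1", n_perm = 50)
  expect_equal(r$p_value, 1)
  expect_true(r$monomorphic)

  # five AB heterozygotes: exact p from full enumeration of all re-pairings
  allhet <- make_ds(cbind(rep("1/2", 5)), rep("A", 5))
  stats_all <- enumerate_hwe_p(c(rep(1, 5), rep(2, 5)))
  t_obs <- 5 * log(2) - lfactorial(5)
  p_exact <- mean(stats_all <= t_obs + 1e-9)
  expect_equal(p_exact, 120 / 945, tolerance = 1e-12)
  n_perm <- 20000
  r2 <- hwe_test(allhet, "A", "loc1", n_perm = n_perm, seed = 7)
  mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(r2$p_value - p_exact), 2 * mc_se)
})

test_that("HWE p-values are approximately uniform under random mating", {
  set.seed(42)
  # vary allele frequencies across replicates so the discrete p-value atoms
  # of the exact test mix into a near-continuous null distribution
  ps <- replicate(200, {
    pr <- as.vector(stats::rgamma(4, 1)); pr <- pr / sum(pr)
    g1 <- sample(1:4, 50, TRUE, prob = pr)
    g2 <- sample(1:4, 50, TRUE, prob = pr)
    ds <- genotype_dataset(matrix(pmin(g1, g2)), matrix(pmax(g1, g2)),
                           "l1", sprintf("i%d", 1:50), rep("A", 50))
    hwe_test(ds, "A", "l1", n_perm = 400)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("LD test flags duplicated loci and passes monomorphic/null cases", {
  set.seed(5)
  g1 <- sample(1:4, 50, TRUE); g2 <- sample(1:4, 50, TRUE)
  dup <- genotype_dataset(cbind(pmin(g1, g2), pmin(g1, g2)),
                          cbind(pmax(g1, g2), pmax(g1, g2)),
                          c("la", "lb"), sprintf("i%d", 1:50), rep("A", 50))
  expect_lte(ld_test(dup, "A", "la", "lb", n_perm = 1000, seed = 1)$p_value,
             0.05)

  mono2 <- make_ds(cbind(c("1/2", "2/2", "1/1"), rep("3/3", 3)), rep("A", 3))
  expect_equal(ld_test(mono2, "A", "loc1", "loc2", n_perm = 50)$p_value, 1)

  # independent loci: p approximately uniform (frequencies vary across
  # replicates to smooth the discrete permutation support)
  set.seed(9)
  ps <- replicate(150, {
    pr1 <- stats::rgamma(3, 1); pr1 <- pr1 / sum(pr1)
    pr2 <- stats::rgamma(3, 1); pr2 <- pr2 / sum(pr2)
    a <- sample(1:3, 40, TRUE, prob = pr1); b <- sample(1:3, 40, TRUE, prob = pr1)
    c1 <- sample(1:3, 40, TRUE, prob = pr2); c2 <- sample(1:3, 40, TRUE, prob = pr2)
    ds <- genotype_dataset(cbind(pmin(a, b), pmin(c1, c2)),
                           cbind(pmax(a, b), pmax(c1, c2)),
                           c("la", "lb"), sprintf("i%d", 1:40), rep("A", 40))
    ld_test(ds, "A", "la", "lb", n_perm = 300)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Weir-Cockerham theta hits its boundary cases and the hand oracle", {
  # fixed difference: theta = 1
  fix <- make_ds(cbind(c("1/1", "1/1", "2/2", "2/2")),
                 c("A", "A", "B", "B"))
  expect_equal(weir_cockerham_fst(fix, c("A", "B"))$theta, 1)

  # group B an exact copy of group A: theta <= 0, permutation p > 0.05
  set.seed(13)
  g1 <- sample(1:5, 30, TRUE); g2 <- sample(1:5, 30, TRUE)
  copy <- genotype_dataset(matrix(c(pmin(g1, g2), pmin(g1, g2))),
                           matrix(c(pmax(g1, g2), pmax(g1, g2))),
                           "l1", sprintf("i%d", 1:60),
                           rep(c("A", "B"), each = 30))
  r <- weir_cockerham_fst(copy, c("A", "B"), n_perm = 199, seed = 2)
  expect_lte(r$theta, 0)
  expect_gt(r$p_value, 0.05)

  # 2x2-individual toy vs step-by-step 1984 component arithmetic
  # pop A {1/1, 1/2}, pop B {2/2, 1/2}: a = 0.125, b = 0, c = 0.5
  toy <- make_ds(cbind(c("1/1", "1/2", "2/2", "1/2")),
                 c("A", "A", "B", "B"))
  rt <- weir_cockerham_fst(toy, c("A", "B"))
  expect_equal(rt$per_locus$a, 0.125, tolerance = 1e-12)
  expect_equal(rt$per_locus$b, 0, tolerance = 1e-12)
  expect_equal(rt$per_locus$c, 0.5, tolerance = 1e-12)
  expect_equal(rt$theta, 0.2, tolerance = 1e-12)

  # monomorphic loci are excluded and reported
  withmono <- make_ds(cbind(c("1/1", "1/1", "2/2", "2/2"), rep("7/7", 4)),
                      c("A", "A", "B", "B"))
  rm <- weir_cockerham_fst(withmono, c("A", "B"))
  expect_identical(rm$excluded_loci, "loc2")
  expect_equal(rm$theta, 1)
})

test_that("exact differentiation matches the hypergeometric oracle and combines per Fisher", {
  # identical allele counts: p near 1
  same <- make_ds(cbind(c("1/2", "1/2", "1/2", "1/2")),
                  c("A", "A", "B", "B"))
  r <- exact_differentiation(same, "A", "B", n_perm = 400, seed = 4)
  expect_gt(r$per_locus$p_value, 0.5)

  # monomorphic locus: p = 1 and Fisher combination equals per-locus p at L = 1
  mono <- make_ds(cbind(rep("1/1", 4)), c("A", "A", "B", "B"))
  rm <- exact_differentiation(mono, "A", "B", n_perm = 50)
  expect_equal(rm$per_locus$p_value, 1)
  expect_equal(rm$chi_sq, 0)
  expect_equal(rm$p_combined, 1)

  # Fisher-combined p equals the per-locus p when L = 1
  two <- make_ds(cbind(c("1/1", "1/2", "2/2", "2/2")), c("A", "A", "B", "B"))
  r1 <- exact_differentiation(two, "A", "B", n_perm = 500, seed = 6)
  expect_equal(r1$p_combined, r1$per_locus$p_value, tolerance = 1e-12)

  # 2x2 allele table (10,0 vs 0,10): compare with the exact two-sided
  # Fisher probability-tail p-value
  split <- make_ds(cbind(c(rep("1/1", 5), rep("2/2", 5))),
                   rep(c("A", "B"), each = 5))
  p_oracle <- stats::fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value
  n_perm <- 20000
  rs <- exact_differentiation(split, "A", "B", n_perm = n_perm, seed = 8)
  mc_se <- sqrt(p_oracle * (1 - p_oracle) / n_perm)
  # the add-one smoothing contributes up to ~2/(n_perm + 1) at this extreme tail
  expect_lt(abs(rs$per_locus$p_value - p_oracle), 2 * mc_se + 2 / (n_perm + 1))
})

test_that("permutation p-values always respect the add-one floor", {
  set.seed(77)
  ds <- make_bn_pair(0.2, 20, n_loci = 4, seed = 78)
  r <- weir_cockerham_fst(ds, c("A", "B"), n_perm = 49, seed = 79)
  expect_gte(r$p_value, 1 / 50)
  expect_lte(r$p_value, 1)
  e <- exact_differentiation(ds, "A", "B", n_perm = 49, seed = 80)
  expect_true(all(e$per_locus$p_value >= 1 / 50 & e$per_locus$p_value <= 1))
})

test_that("the HWE table wrapper covers every group-locus cell with a family-wise flag", {
  ds <- make_bn_pair(0.05, 15, n_loci = 3, seed = 88)
  tab <- hwe_table(ds, n_perm = 100, seed = 89)
  expect_equal(nrow(tab), 2 * 3)
  expect_true(all(tab$p_value >= 1 / 101 & tab$p_value <= 1))
  expect_identical(tab$significant, bonferroni_significant(tab$p_value))
})

test_that("Bonferroni flags use the per-table corrected level", {
  p <- c(0.001, 0.01, 0.2, 0.04)
  expect_identical(bonferroni_significant(p, alpha = 0.05),
                   c(TRUE, TRUE, FALSE, FALSE))
})
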