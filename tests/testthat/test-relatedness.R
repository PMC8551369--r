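# independent single-locus Queller-Goodnight implementation used as an oracle:
# explicit allele lists and Kronecker deltas, no matrix algebra
qg_oracle <- function(dosA, dosB, p_alt) {
  alleles <- function(d) c(rep(1, d), rep(0, 2 - d))
  pfreq <- function(a) ifelse(a == 1, p_alt, 1 - p_alt)
  dir_num <- function(x, y) {
    ax <- alleles(x); ay <- alleles(y)
    0.5 * sum(outer(ax, ay, "==")) - sum(pfreq(ax))
  }
  dir_den <- function(x) 1 + (alleles(x)[1] == alleles(x)[2]) - sum(pfreq(alleles(x)))
  num <- dir_num(dosA, dosB) + dir_num(dosB, dosA)
  den <- dir_den(dosA) + dir_den(dosB)
  if (abs(den) < 1e-12) return(NA_real_)
  num / den
}

test_that("Loiselle estimator reproduces the hand-computed single-locus case", {
  # p = 0.5 over 11 individuals, pair (x_i = 1, x_j = 0):
  # ((1-.5)(0-.5) + .25/10) / .25 = -0.9
  g <- gm(2, 0, 2, 2, 2, 2, 1, 0, 0, 0, 0, nrow = 11)
  k <- loiselle_kinship(g)
  expect_equal(k$values[1, 2], -0.9)
  expect_equal(k$values[2, 1], -0.9)        # symmetric
})

test_that("Ritland estimator reproduces the hand-computed single-locus case", {
  # pair of identical homozygotes at p = 0.5: 1/0.5 - 1 = 1
  g <- gm(0, 0, 2, 2, 1, 1, nrow = 6)
  expect_equal(ritland_kinship(g)$values[1, 2], 1)
})

test_that("Queller-Goodnight agrees with a brute-force second implementation", {
  set.seed(71)
  for (rep in 1:20) {
    n <- 8
    dos <- matrix(rbinom(n, 2, runif(1, 0.2, 0.8)), n, 1)
    if (length(unique(dos)) == 1) next
    g <- genotype_matrix(dos)
    p <- sum(dos) / (2 * n)
    k <- queller_goodnight(g)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(k$values[i, j], qg_oracle(dos[i], dos[j], p),
                   tolerance = 1e-12)
    }
  }
  # identical heterozygote pair at p = 0.5 is 0/0: undefined, flagged
  g <- gm(1, 1, 0, 2, nrow = 4)
  expect_true(is.na(queller_goodnight(g)$values[1, 2]))
})

test_that("all estimators are symmetric and invariant to allele relabeling", {
  g <- random_hw_matrix(12, 120, seed = 8)
  flip <- sample(ncol(g), 40)
  x2 <- unclass(g); x2[, flip] <- 2 - x2[, flip]
  g2 <- genotype_matrix(x2)
  for (fun in list(loiselle_kinship, ritland_kinship, queller_goodnight)) {
    k1 <- fun(g, keep_parts = FALSE)$values
    k2 <- fun(g2, keep_parts = FALSE)$values
    expect_equal(k1, t(k1))
    expect_equal(k1, k2, tolerance = 1e-10)
  }
})

test_that("multilocus values reassemble from retained per-locus parts", {
  g <- degrade(random_hw_matrix(10, 60, seed = 18), missing_rate = 0.1,
               seed = 19)
  for (fun in list(loiselle_kinship, ritland_kinship, queller_goodnight)) {
    k <- fun(g, keep_parts = TRUE)
    rebuilt <- unname(rowSums(k$num_parts) / rowSums(k$den_parts))
    direct <- k$values[cbind(k$pair_i, k$pair_j)]
    expect_equal(rebuilt, direct, tolerance = 1e-10)
  }
})

test_that("pedigree calibration hits theoretical kinship expectations", {
  cases <- list(half_sib = 0.125, full_sib = 0.25, unrelated = 0)
  for (rel in names(cases)) {
    g <- simulate_pedigree_pairs(rel, n_pairs = 150, n_loci = 1000,
                                 n_reference = 60, seed = 100 + nchar(rel))
    k <- loiselle_kinship(g, keep_parts = FALSE)
    expect_lt(abs(pair_means(g, k) - cases[[rel]]), 0.015)
  }
  # Queller-Goodnight on the relationship scale: full sibs ~0.5, half ~0.25
  g <- simulate_pedigree_pairs("full_sib", 150, 1000, n_reference = 60,
                               seed = 301)
  expect_lt(abs(pair_means(g, queller_goodnight(g, keep_parts = FALSE)) - 0.5),
            0.025)
  g <- simulate_pedigree_pairs("half_sib", 150, 1000, n_reference = 60,
                               seed = 302)
  expect_lt(abs(pair_means(g, queller_goodnight(g, keep_parts = FALSE)) - 0.25),
            0.025)
  # Ritland: parent-offspring pairs on the kinship scale
  g <- simulate_pedigree_pairs("parent_offspring", 150, 1000,
                               n_reference = 60, seed = 303)
  expect_lt(abs(pair_means(g, ritland_kinship(g, keep_parts = FALSE)) - 0.25),
            0.02)
})

test_that("Ritland is more downward biased than Loiselle with rare alleles", {
  g <- simulate_pedigree_pairs("full_sib", 120, 1500,
                               freq_range = c(0.005, 0.04),
                               n_reference = 80, seed = 404)
  dev_l <- pair_means(g, loiselle_kinship(g, keep_parts = FALSE)) - 0.25
  dev_r <- pair_means(g, ritland_kinship(g, keep_parts = FALSE)) - 0.25
  expect_lt(dev_r, dev_l)   # directional property only
})

test_that("relationship/kinship conversion matches the defining identity", {
  expect_equal(f_to_r(0.125, f_i = 0), 0.25)
  expect_equal(f_to_r(0.155, f_i = 0.071), 0.2894, tolerance = 1e-3)
  expect_equal(r_to_f(f_to_r(0.2, 0.1), 0.1), 0.2)
  expect_error(r_to_f(0.5, f_i = -1), "-1")
})

test_that("inbreeding estimator matches hand computation and pedigree truth", {
  # individual heterozygous at every locus, all p = 0.5 -> F = -1
  g <- gm(1, 1, 1, 1,
          1, 1, 1, 1,
          0, 0, 0, 0,
          2, 2, 2, 2, nrow = 4)
  ib <- inbreeding(g)
  expect_equal(ib$per_individual$f[1], -1)
  expect_equal(mean(ib$per_individual$f), ib$mean_f)
  expect_true(ib$ci95[1] <= ib$mean_f && ib$mean_f <= ib$ci95[2])
  # selfed offspring of outbred parents: F ~ 0.5
  set.seed(77)
  q <- runif(1500, 0.2, 0.8)
  parents <- matrix(rbinom(60 * 1500, 2, rep(q, each = 60)), 60)
  gam <- function(m) (m == 2) + (m == 1) * rbinom(length(m), 1, 0.5)
  selfed <- matrix(gam(parents) + gam(parents), 60)
  both <- genotype_matrix(rbind(parents, selfed))
  f_all <- inbreeding(both)$per_individual$f
  expect_equal(mean(f_all[61:120]) - mean(f_all[1:60]), 0.5, tolerance = 0.05)
  # HWE population: F ~ 0
  expect_equal(inbreeding(random_hw_matrix(80, 800, seed = 5))$mean_f, 0,
               tolerance = 0.02)
})

test_that("jackknife SE behaves like a resampling SE should", {
  # constant parts -> zero SE
  jc <- jackknife_ratio_ci(rep(2, 10), rep(4, 10))
  expect_equal(jc$estimate, 0.5)
  expect_equal(jc$se, 0)
  # for a plain mean (unit denominators) the jackknife SE equals the
  # classical SE of the mean
  set.seed(31)
  xs <- rnorm(40)
  jc2 <- jackknife_ratio_ci(xs, rep(1, 40))
  expect_equal(jc2$se, stats::sd(xs) / sqrt(40), tolerance = 1e-10)
  # duplicating loci k times shrinks the SE like 1/sqrt(k)
  jc4 <- jackknife_ratio_ci(rep(xs, 4), rep(1, 160))
  expect_equal(jc4$se / jc2$se, 0.5, tolerance = 0.02)
  expect_error(jackknife_ratio_ci(1, 1), "at least 2")
})
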