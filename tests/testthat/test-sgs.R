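test_that("pairwise distances are Euclidean, translation invariant, flagged", {
  sam <- data.frame(id = c("a", "b", "c"), x = c(0, 3, 0), y = c(0, 4, 0),
                    stage = "adult", reproductive = 1)
  d <- pairwise_distances(sam)
  expect_equal(d["a", "b"], 5)
  expect_equal(d, t(d))
  shifted <- sam; shifted$x <- shifted$x + 100; shifted$y <- shifted$y - 50
  expect_equal(unname(pairwise_distances(shifted)), unname(d))
  expect_equal(nrow(attr(d, "zero_distance_pairs")), 1L)  # a and c coincide
  bad <- sam; bad$y[2] <- NA
  expect_error(pairwise_distances(bad), "b")
  # torus metric wraps across the boundary
  sam2 <- data.frame(id = c("p", "q"), x = c(1, 99), y = c(0, 0))
  expect_equal(pairwise_distances(sam2, arena = c(100, 100))["p", "q"], 2)
})

test_that("equal-count distance classes balance pairs even under ties", {
  d <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  dc <- make_distance_classes(d, k = 6)
  expect_equal(dc$bounds$n_pairs, rep(2L, 6))
  dtied <- c(rep(5, 9), 1, 2, 3)
  dc2 <- make_distance_classes(dtied, k = 4)
  expect_lte(diff(range(dc2$bounds$n_pairs)), 1L)
  expect_equal(sum(dc2$bounds$n_pairs), length(dtied))
  expect_error(make_distance_classes(d, k = 1), "at least 2")
  # explicit bounds path
  dc3 <- make_distance_classes(d, breaks = c(6, 12))
  expect_equal(dc3$bounds$n_pairs, c(6L, 6L))
})

test_that("a noiseless log-linear kinship field is recovered exactly", {
  set.seed(61)
  n <- 15
  sam <- random_samples(sprintf("i%02d", 1:n), arena = c(200, 200), seed = 62)
  d <- pairwise_distances(sam)
  b_true <- -0.04; a_true <- 0.1
  vals <- matrix(NA_real_, n, n, dimnames = list(sam$id, sam$id))
  vals[upper.tri(vals)] <- a_true + b_true * log(d[upper.tri(d)])
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  kin <- structure(list(estimator = "loiselle", values = vals,
                        n_loci = NULL, ids = sam$id, loci = "synthetic"),
                   class = "kinship_matrix")
  reg <- sgs_regression(kin, d, n_classes = 3)
  expect_equal(reg$b, b_true, tolerance = 1e-12)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)
})

test_that("Sp, Nb, De and sigma satisfy their defining algebra", {
  expect_lt(abs(sp_statistic(-0.033, 0.053) - 0.0349), 1e-4)
  expect_equal(sp_statistic(0, 0.1), 0)
  expect_lt(abs(sp_statistic(-0.05499, 0.1553) - 0.0651), 1e-4)
  expect_error(sp_statistic(-0.1, 1), "below 1")

  expect_equal(neighborhood_size(1), 1)
  expect_lt(abs(neighborhood_size(0.0208) - 48.08), 0.01)
  expect_error(neighborhood_size(-0.01), "undefined")

  de <- effective_density(0.79, 0.30)
  expect_equal(de$effective_density_de, 0.237)
  expect_equal(effective_density(0.37, 0.30)$effective_density_de, 0.111)
  expect_equal(round(34 / 115, 2), 0.30)   # Ne/N from the census counts
  expect_error(effective_density(-1, 0.3))

  # unit case: Nb = 4*pi at De = 1 ind/m^2 gives sigma = 1 m
  expect_equal(dispersal_sigma(4 * pi, 1e4), 1)
  # full round trip: sigma^2 * 4 pi De = Nb and Nb * Sp = 1
  sp <- 0.0651
  nb <- neighborhood_size(sp)
  sig <- dispersal_sigma(nb, effective_density(0.37, 0.30))
  expect_equal(sig^2 * 4 * pi * effective_density(0.37, 0.30)$de_per_m2, nb)
  expect_equal(nb * sp, 1)
})

test_that("permutation test is deterministic, calibrated and powerful", {
  # determinism
  g <- random_hw_matrix(20, 80, seed = 91)
  sam <- random_samples(rownames(g), seed = 92)
  kin <- loiselle_kinship(g, keep_parts = FALSE)
  d <- pairwise_distances(sam)
  p1 <- permutation_test(kin, d, n_perm = 300, seed = 7)$p
  p2 <- permutation_test(kin, d, n_perm = 300, seed = 7)$p
  expect_identical(p1, p2)
  expect_error(permutation_test(kin, d, n_perm = 50), "at least 100")

  # null calibration: p-values uniform over replicates (no spatial signal)
  set.seed(93)
  ps <- vapply(1:200, function(r) {
    g <- random_hw_matrix(15, 50)
    sam <- random_samples(rownames(g))
    k <- loiselle_kinship(g, keep_parts = FALSE)
    permutation_test(k, pairwise_distances(sam), n_perm = 199)$p
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)

  # power under strong isolation by distance
  sim <- simulate_ibd_population(sigma_true = 15, density = 50,
                                 n_generations = 20, arena = c(300, 300),
                                 n_loci = 300, seed = 94)
  keep <- sample(nrow(sim$genotypes), 60)
  gs <- subset_genotypes(sim$genotypes, individuals = keep)
  ks <- loiselle_kinship(gs, keep_parts = FALSE)
  ds <- pairwise_distances(sim$samples[keep, ], arena = sim$arena)
  expect_lte(permutation_test(ks, ds, n_perm = 999, seed = 1)$p, 0.01)
})

test_that("class means weighted by pair counts conserve the global mean", {
  g <- degrade(random_hw_matrix(18, 200, seed = 111), missing_rate = 0.05,
               seed = 112)
  sam <- random_samples(rownames(g), seed = 113)
  fit <- sgs(g, sam, estimator = "loiselle", n_perm = 0)
  w <- fit$classes$n_pairs
  expect_equal(sum(w * fit$classes$mean_kinship) / sum(w),
               mean(fit$pairs$kinship), tolerance = 1e-10)
})

test_that("the sgs() fit object carries coherent derived quantities", {
  sim <- simulate_ibd_population(sigma_true = 15, density = 50,
                                 n_generations = 20, arena = c(300, 300),
                                 n_loci = 400, seed = 121)
  keep <- sample(nrow(sim$genotypes), 70)
  g <- subset_genotypes(sim$genotypes, individuals = keep)
  sam <- sim$samples[keep, ]
  d <- pairwise_distances(sam, arena = sim$arena)
  fit <- sgs(g, sam, estimator = "loiselle", n_perm = 200,
             census_density = sim$density_per_ha, ne_ratio = 1,
             distances = d, seed = 5)
  expect_s3_class(fit, "sgs")
  expect_equal(fit$sp, -fit$b / (1 - fit$f1))
  expect_equal(fit$nb, 1 / fit$sp)
  expect_equal(fit$sigma_m^2 * 4 * pi * fit$density$de_per_m2, fit$nb)
  expect_true(fit$sp_ci[1] <= fit$sp && fit$sp <= fit$sp_ci[2])
  co <- coef(fit)
  expect_named(co, c("f1", "b", "r_squared", "sp", "nb", "sigma_m"))
  expect_output(print(fit), "Sp")
  expect_output(summary(fit), "Distance classes")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("queller-goodnight fits convert to the kinship scale for Sp", {
  g <- random_hw_matrix(16, 150, seed = 131)
  sam <- random_samples(rownames(g), seed = 132)
  fit_qg <- sgs(g, sam, estimator = "queller_goodnight", n_perm = 0)
  fit_l <- sgs(g, sam, estimator = "loiselle", n_perm = 0)
  # same scale after conversion: F1 values comparable (both near 0 here)
  expect_lt(abs(fit_qg$f1 - fit_l$f1), 0.1)
  expect_false(is.na(fit_qg$sp))
})
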