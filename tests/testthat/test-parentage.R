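test_that("Mendelian transition probabilities are correct and normalized", {
  # offspring het, parent hom-ref: needs an alt gamete from the population
  expect_equal(transition_prob(1, 0, 0.3), 0.3)
  expect_equal(transition_prob(2, 0, 0.3), 0)   # impossible transmission
  for (gp in 0:2) {
    expect_equal(sum(transition_prob(0:2, gp, 0.37)), 1)
  }
})

test_that("single-parent LOD matches hand computation and exclusion limits", {
  # one locus, p = 0.5, offspring and candidate hom-ref, e = 0:
  # ln(P(0|0)/P(0)) = ln(0.5/0.25) = ln 2
  expect_equal(lod_single_parent(0, 0, 0.5, e = 0), log(2))
  expect_identical(lod_single_parent(2, 0, 0.5, e = 0), -Inf)
  lod_e <- lod_single_parent(2, 0, 0.5, e = 0.01)
  expect_true(is.finite(lod_e) && lod_e < 0)
  # hand computation of the error-model mixture at the incompatible locus:
  # ln(((1-e)^2 * 0 + (1-(1-e)^2) * q^2) / q^2)
  expect_equal(lod_e, log(1 - 0.99^2))
  # no shared genotyped locus -> undefined
  expect_true(is.na(lod_single_parent(NA, 0, 0.5)))
})

test_that("LODs add over loci and ignore missing genotypes", {
  freqs <- c(0.3, 0.6)
  two <- lod_single_parent(c(0, 1), c(0, 1), freqs, e = 0.01)
  one_a <- lod_single_parent(c(0, NA), c(0, 1), freqs, e = 0.01)
  one_b <- lod_single_parent(c(NA, 1), c(0, 1), freqs, e = 0.01)
  expect_equal(two, one_a + one_b)
  twop <- lod_parent_pair(c(0, 1), c(0, 1), c(1, 1), freqs, e = 0.01)
  pa <- lod_parent_pair(c(0, NA), c(0, 1), c(1, 1), freqs, e = 0.01)
  pb <- lod_parent_pair(c(NA, 1), c(0, 1), c(1, 1), freqs, e = 0.01)
  expect_equal(twop, pa + pb)
  # allele-label swap invariance: flip dosages and frequencies together
  expect_equal(lod_single_parent(c(2, 1), c(2, 1), 1 - freqs, e = 0.01), two)
})

test_that("parent-pair LOD respects exclusion and favors true selfing", {
  expect_identical(lod_parent_pair(2, 0, 1, 0.5, e = 0), -Inf)
  # simulated selfed offspring: self-pair LOD beats both single LODs
  set.seed(41)
  q <- runif(400, 0.2, 0.8)
  parent <- rbinom(400, 2, q)
  gam <- function(g) (g == 2) + (g == 1) * rbinom(length(g), 1, 0.5)
  off <- gam(parent) + gam(parent)
  lod_pair_self <- lod_parent_pair(off, parent, parent, q, e = 0.01)
  lod_single <- lod_single_parent(off, parent, q, e = 0.01)
  expect_gt(lod_pair_self, lod_single)
})

test_that("the Delta criterion simulation is deterministic and scales with information", {
  q <- runif(80, 0.2, 0.8)
  cfg <- parentage_config(n_sim = 1000, prop_sampled = 1, error_rate = 0)
  d1 <- simulate_delta_crit(q, n_candidates = 10, cfg, seed = 3)
  d2 <- simulate_delta_crit(q, n_candidates = 10, cfg, seed = 3)
  expect_identical(d1$delta_single, d2$delta_single)
  expect_identical(d1$d_pair, d2$d_pair)
  # strong information: all parents sampled, many loci -> success ~ 100%,
  # criterion ~ 0
  set.seed(11)
  q_big <- runif(600, 0.2, 0.8)
  d_strong <- simulate_delta_crit(q_big, n_candidates = 10, cfg, seed = 5)
  expect_gte(d_strong$success_pair, 0.99)
  expect_equal(d_strong$delta_pair, 0)
  # 3 loci: low power, criterion large or unattainable
  cfg90 <- parentage_config(n_sim = 1000, prop_sampled = 0.9)
  d_weak <- suppressWarnings(
    simulate_delta_crit(c(0.5, 0.4, 0.3), n_candidates = 20, cfg90, seed = 6))
  expect_gt(d_weak$delta_pair, d_strong$delta_pair)
  expect_error(parentage_config(n_sim = 10), "n_sim")
})

test_that("assignment recovers a simulated family exactly at high information", {
  cfg <- sim_config(n_adults = 25, n_reproductive = 18, n_offspring = 12,
                    n_loci = 400, arena = c(400, 400), selfing_rate = 0.25,
                    missing_rate = 0, error_rate = 0, maf_floor = 0.05,
                    seed = 15)
  pop <- simulate_spatial_population(cfg)
  pc <- parentage_config(error_rate = 0, prop_sampled = 1, n_sim = 1000)
  fit <- parentage(pop$genotypes, pop$samples, pc, seed = 21)
  m <- merge(pop$pedigree, fit$assignments, by = "offspring_id")
  same_pair <- (m$maternal_id.x == m$maternal_id.y &
                  m$paternal_id.x == m$paternal_id.y) |
    (m$maternal_id.x == m$paternal_id.y & m$paternal_id.x == m$maternal_id.y)
  expect_true(all(same_pair))
  expect_equal(fit$counts$selfing_rate, mean(pop$pedigree$selfed))
  # an offspring cannot also be a candidate
  bad <- pop$samples
  bad$reproductive[bad$stage == "seedling"] <- 1
  expect_error(parentage(pop$genotypes, bad, pc, seed = 1), "candidate")
})

test_that("offspring with no compatible candidate gets no parent at e = 0", {
  set.seed(51)
  q <- rep(0.5, 60)
  dos <- rbind(matrix(0, 4, 60),  # candidates all hom-ref
               rep(2, 60))        # offspring hom-alt everywhere: excluded
  rownames(dos) <- c(paste0("c", 1:4), "off")
  g <- genotype_matrix(dos)
  ids <- rownames(g)
  sam <- data.frame(id = ids, x = seq_along(ids), y = 0,
                    stage = c(rep("adult", 4), "seedling"),
                    reproductive = c(rep(1, 4), 0))
  pc <- parentage_config(error_rate = 0, prop_sampled = 1, n_sim = 1000)
  dc <- list(delta_single = 0, delta_pair = 0)
  asg <- assign_parentage(g, sam, ids[5], ids[1:4], freqs = q, cfg = pc,
                          delta_crit = dc)
  expect_equal(asg$category, "no_parent")
})

test_that("non-exclusion probability matches Monte-Carlo exclusion frequency", {
  # exhaustive enumeration at p = 0.5 against simulated random trios
  q <- 0.5
  per <- non_exclusion_pp(q)$per_locus
  set.seed(61)
  n_mc <- 40000
  go <- rbinom(n_mc, 1, 0.5) + rbinom(n_mc, 1, 0.5)  # HW offspring
  g1 <- rbinom(n_mc, 2, q); g2 <- rbinom(n_mc, 2, q)
  u <- g1 / 2; v <- g2 / 2
  t2 <- ifelse(go == 0, (1 - u) * (1 - v),
               ifelse(go == 1, u * (1 - v) + (1 - u) * v, u * v))
  expect_equal(per, mean(t2 > 0), tolerance = 0.01)
  # multi-locus: product rule, monomorphic loci uninformative
  expect_equal(non_exclusion_pp(c(0.5, 0))$p_p, per)
  many <- non_exclusion_pp(rep(0.3, 50))
  few <- non_exclusion_pp(rep(0.3, 10))
  expect_lt(many$p_p, few$p_p)
})

test_that("cryptic gene flow follows 1 - (1 - Pp)^n and is monotone", {
  expect_equal(cryptic_gene_flow(0, 34), 0)
  expect_equal(cryptic_gene_flow(0.001, 34), 1 - 0.999^34)
  expect_lt(cryptic_gene_flow(2.603e-227, 34), 1e-224)
  grid_p <- c(0, 1e-6, 1e-3, 0.1, 0.9, 1)
  vals <- vapply(grid_p, cryptic_gene_flow, 0, n = 10)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vapply(1:5, function(n)
    cryptic_gene_flow(0.01, n), 0)) >= 0))
})

test_that("dispersal summary implements the variance combination rule", {
  asg <- data.frame(
    offspring_id = c("o1", "o2", "o3", "o4"),
    maternal_id = c("m1", "m2", "m3", NA),
    paternal_id = c("p1", "p2", NA, NA),
    category = c("both_parents", "both_parents", "single_parent", "no_parent"),
    seed_distance_m = c(10, 20, 15, NA),
    pollen_distance_m = c(50, 80, NA, NA))
  ds <- dispersal_summary(asg)
  expect_equal(ds$m_p, 0.25)
  expect_equal(ds$m_s, 0.25)
  expect_equal(ds$sigma_rt,
               sqrt(0.5 * var(c(50, 80)) + var(c(10, 20, 15))))
  # var(pollen) = 2, var(seed) = 1 -> sigma_rt = sqrt(2)
  asg2 <- asg[1:2, ]
  asg2$seed_distance_m <- c(10, 10 + sqrt(2))
  asg2$pollen_distance_m <- c(50, 52)
  expect_equal(dispersal_summary(asg2)$sigma_rt, sqrt(2))
  # all distances equal -> zero
  asg3 <- asg2
  asg3$seed_distance_m <- c(5, 5); asg3$pollen_distance_m <- c(9, 9)
  expect_equal(dispersal_summary(asg3)$sigma_rt, 0)
})
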