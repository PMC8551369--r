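#' Simulation configuration for a spatially explicit population
#'
#' Defaults emulate a small, spatially mapped stand of a hermaphroditic
#' tropical tree: 99 adults (34 reproductive) plus 16 seedlings in a ~125 ha
#' arena (census adult density 0.79 ind/ha), 3,000 biallelic loci with
#' founder allele frequencies uniform on (0.05, 0.95), a selfing rate of
#' 0.375, exponential pollen and seed kernels with mean distances of 70 m and
#' 20 m (the scale of observed pollination and seed-dispersal distances in
#' such stands), 1% genotyping error, 5% missing data and a MAF ascertainment
#' floor of 0.05.
#'
#' @param n_adults total adults; the first \code{n_reproductive} are flagged
#'   reproductive and act as candidate parents.
#' @param n_reproductive number of reproductive adults.
#' @param n_offspring number of seedlings.
#' @param arena \code{c(width, height)} in metres.
#' @param n_loci number of biallelic loci before ascertainment.
#' @param freq_range founder allele-frequency range (uniform draw).
#' @param selfing_rate probability a seedling is selfed.
#' @param pollen_kernel,seed_kernel lists \code{list(family, scale)} with
#'   family \code{"exponential"} or \code{"gaussian"} and scale in metres.
#' @param missing_rate,error_rate per-genotype missingness and error.
#' @param maf_floor ascertainment: loci below this realized MAF are dropped.
#' @param seed integer seed.
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_adults = 99, n_reproductive = 34, n_offspring = 16,
                       arena = c(1118, 1118), n_loci = 3000,
                       freq_range = c(0.05, 0.95), selfing_rate = 0.375,
                       pollen_kernel = list(family = "exponential", scale = 70),
                       seed_kernel = list(family = "exponential", scale = 20),
                       missing_rate = 0.05, error_rate = 0.01,
                       maf_floor = 0.05, seed = 1L) {
  stopifnot(n_adults >= n_reproductive, n_reproductive >= 1, n_offspring >= 0,
            all(arena > 0), n_loci >= 1,
            selfing_rate >= 0, selfing_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1,
            maf_floor >= 0, maf_floor <= 0.5,
            pollen_kernel$family %in% c("exponential", "gaussian"),
            seed_kernel$family %in% c("exponential", "gaussian"),
            pollen_kernel$scale > 0, seed_kernel$scale > 0)
  structure(as.list(environment()), class = "sim_config")
}

# one gamete per genotype entry (dosage matrix or vector)
.gamete <- function(g) {
  out <- (g == 2) + (g == 1) * stats::rbinom(length(g), 1, 0.5)
  if (is.matrix(g)) out <- matrix(out, nrow(g), ncol(g))
  out
}

# HW genotypes: n individuals x L loci at alt frequencies q
.hw_genotypes <- function(n, q) {
  matrix(stats::rbinom(n * length(q), 2, rep(q, each = n)), n, length(q))
}

.kernel_draw <- function(kernel, n) {
  r <- switch(kernel$family,
              exponential = stats::rexp(n, rate = 1 / kernel$scale),
              gaussian = abs(stats::rnorm(n, 0, kernel$scale)))
  theta <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(theta), r * sin(theta))
}

.kernel_density <- function(kernel, d) {
  switch(kernel$family,
         exponential = exp(-d / kernel$scale),
         gaussian = exp(-d^2 / (2 * kernel$scale^2)))
}

#' Simulate genotype pairs of a known pedigree relationship
#'
#' Founders are drawn under Hardy-Weinberg at allele frequencies sampled
#' uniformly from \code{freq_range}; descent follows the minimal pedigree of
#' the requested relationship. Expected kinship: parent-offspring and
#' full sibs 0.25, half sibs 0.125, first cousins 0.0625, first cousins once
#' removed 0.03125, second cousins (shared great-grandparental couple)
#' 0.015625, unrelated 0.
#'
#' @param relationship one of \code{"unrelated"}, \code{"parent_offspring"},
#'   \code{"full_sib"}, \code{"half_sib"}, \code{"first_cousin"},
#'   \code{"first_cousin_once_removed"}, \code{"second_cousin"}.
#' @param n_pairs number of independent pairs.
#' @param n_loci number of loci (>= 100 recommended).
#' @param freq_range allele-frequency range of the uniform founder sampler.
#' @param n_reference additional unrelated individuals included for allele
#'   frequency estimation.
#' @param seed integer seed.
#' @return A \code{\link{genotype_matrix}} of 2 x n_pairs + n_reference
#'   individuals with attributes \code{pairs} (two-column id matrix) and
#'   \code{expected_kinship}.
#' @export
simulate_pedigree_pairs <- function(relationship, n_pairs, n_loci,
                                    freq_range = c(0.1, 0.9),
                                    n_reference = 100, seed = NULL) {
  kin_expect <- c(unrelated = 0, parent_offspring = 0.25, full_sib = 0.25,
                  half_sib = 0.125, first_cousin = 0.0625,
                  first_cousin_once_removed = 0.03125,
                  second_cousin = 0.015625)
  if (!relationship %in% names(kin_expect))
    stop("unknown relationship: ", relationship)
  if (!is.null(seed)) set.seed(seed)
  q <- stats::runif(n_loci, freq_range[1], freq_range[2])
  hw <- function() .hw_genotypes(n_pairs, q)
  child <- function(m, f) .gamete(m) + .gamete(f)
  ped <- switch(relationship,
    unrelated = list(hw(), hw()),
    parent_offspring = {
      a <- hw(); list(a, child(a, hw()))
    },
    full_sib = {
      a <- hw(); b <- hw(); list(child(a, b), child(a, b))
    },
    half_sib = {
      a <- hw(); list(child(a, hw()), child(a, hw()))
    },
    first_cousin = {
      g1 <- hw(); g2 <- hw()
      p1 <- child(g1, g2); p2 <- child(g1, g2)
      list(child(p1, hw()), child(p2, hw()))
    },
    first_cousin_once_removed = {
      g1 <- hw(); g2 <- hw()
      p1 <- child(g1, g2); p2 <- child(g1, g2)
      x <- child(p1, hw()); z <- child(p2, hw())
      list(x, child(z, hw()))
    },
    second_cousin = {
      g1 <- hw(); g2 <- hw()
      p1 <- child(g1, g2); p2 <- child(g1, g2)
      c1 <- child(p1, hw()); c2 <- child(p2, hw())
      list(child(c1, hw()), child(c2, hw()))
    })
  ref <- .hw_genotypes(n_reference, q)
  dos <- rbind(ped[[1]], ped[[2]], ref)
  ids <- c(sprintf("pair%04d_a", seq_len(n_pairs)),
           sprintf("pair%04d_b", seq_len(n_pairs)),
           sprintf("ref%04d", seq_len(n_reference)))
  rownames(dos) <- ids
  g <- genotype_matrix(dos)
  attr(g, "pairs") <- cbind(ids[seq_len(n_pairs)],
                            ids[n_pairs + seq_len(n_pairs)])
  attr(g, "expected_kinship") <- unname(kin_expect[relationship])
  attr(g, "relationship") <- relationship
  g
}

#' Degrade a genotype matrix: missingness, error, MAF ascertainment
#'
#' Missing-completely-at-random masking at \code{missing_rate}, per-genotype
#' replacement with a random Hardy-Weinberg genotype at \code{error_rate}
#' (frequencies taken from the undegraded data), then removal of loci whose
#' realized MAF falls below \code{maf_floor}. \code{missing_rate} may be a
#' per-locus vector, which emulates the heterogeneous locus dropout of
#' RAD-style data (many complete loci, a tail of poorly genotyped ones).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param missing_rate scalar or per-locus vector of missingness rates.
#' @param error_rate,maf_floor rates in [0, 1].
#' @param seed integer seed.
#' @return The degraded \code{genotype_matrix}.
#' @export
degrade <- function(g, missing_rate = 0, error_rate = 0, maf_floor = 0,
                    seed = NULL) {
  g <- as_genotype_matrix(g)
  if (!is.null(seed)) set.seed(seed)
  x <- unclass(g)
  n <- nrow(x); l <- ncol(x)
  if (error_rate > 0) {
    q <- colSums(x, na.rm = TRUE) / (2 * colSums(!is.na(x)))
    err <- matrix(stats::runif(n * l) < error_rate, n, l) & !is.na(x)
    if (any(err)) {
      qm <- matrix(rep(q, each = n), n, l)
      x[err] <- stats::rbinom(sum(err), 2, qm[err])
    }
  }
  if (any(missing_rate > 0)) {
    rate <- matrix(rep(missing_rate, length.out = l), n, l, byrow = TRUE)
    x[matrix(stats::runif(n * l), n, l) < rate] <- NA_real_
  }
  out <- genotype_matrix(x, rad_locus = attr(g, "rad_locus"),
                         position = attr(g, "position"))
  if (maf_floor > 0) {
    st <- locus_stats(out, hwe = FALSE)
    out <- subset_genotypes(out, loci = !is.na(st$maf) & st$maf >= maf_floor)
  }
  out
}

#' Simulate a spatially explicit population with known pedigree
#'
#' Adults are placed uniformly in the arena. Each seedling draws its maternal
#' tree uniformly among reproductive adults; with probability
#' \code{selfing_rate} it is selfed, otherwise the paternal tree is chosen
#' among the other reproductive adults with probability proportional to the
#' pollen-kernel density at the inter-tree distance. The seedling is placed
#' at the maternal position plus a seed-kernel displacement (clamped to the
#' arena). Genotypes are Mendelian from Hardy-Weinberg founders, then
#' degraded (error, missingness, MAF ascertainment).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return List with \code{samples} (sample map data frame),
#'   \code{genotypes} (degraded \code{genotype_matrix}),
#'   \code{genotypes_true} (pre-degradation), and \code{pedigree}
#'   (data frame: offspring id, true parents, selfed flag, true seed and
#'   pollen distances).
#' @export
simulate_spatial_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_adults < 1 || cfg$n_loci < 1) stop("need adults and loci")
  set.seed(cfg$seed)
  na <- cfg$n_adults; no <- cfg$n_offspring
  q <- stats::runif(cfg$n_loci, cfg$freq_range[1], cfg$freq_range[2])
  adult_ids <- sprintf("adult_%03d", seq_len(na))
  repro <- c(rep(1, cfg$n_reproductive), rep(0, na - cfg$n_reproductive))
  ax <- stats::runif(na, 0, cfg$arena[1])
  ay <- stats::runif(na, 0, cfg$arena[2])
  ga <- .hw_genotypes(na, q)

  ridx <- which(repro == 1)
  off_ids <- sprintf("seedling_%03d", seq_len(no))
  ox <- oy <- numeric(no)
  go <- matrix(0, no, cfg$n_loci)
  ped <- vector("list", no)
  for (k in seq_len(no)) {
    m <- sample(ridx, 1)
    selfed <- stats::runif(1) < cfg$selfing_rate
    if (selfed || length(ridx) == 1) {
      f <- m
    } else {
      others <- setdiff(ridx, m)
      dmf <- sqrt((ax[others] - ax[m])^2 + (ay[others] - ay[m])^2)
      w <- .kernel_density(cfg$pollen_kernel, dmf)
      f <- if (sum(w) > 0) others[sample.int(length(others), 1, prob = w)]
      else others[which.min(dmf)]
    }
    disp <- .kernel_draw(cfg$seed_kernel, 1)
    ox[k] <- min(max(ax[m] + disp[1], 0), cfg$arena[1])
    oy[k] <- min(max(ay[m] + disp[2], 0), cfg$arena[2])
    go[k, ] <- .gamete(ga[m, ]) + .gamete(ga[f, ])
    ped[[k]] <- data.frame(
      offspring_id = off_ids[k], maternal_id = adult_ids[m],
      paternal_id = adult_ids[f], selfed = (f == m),
      seed_distance_m = sqrt((ox[k] - ax[m])^2 + (oy[k] - ay[m])^2),
      pollen_distance_m = sqrt((ax[f] - ax[m])^2 + (ay[f] - ay[m])^2))
  }

  dos <- rbind(ga, go)
  rownames(dos) <- c(adult_ids, off_ids)
  colnames(dos) <- sprintf("snp_%05d", seq_len(cfg$n_loci))
  g_true <- genotype_matrix(dos)
  g_obs <- degrade(g_true, cfg$missing_rate, cfg$error_rate, cfg$maf_floor)

  samples <- data.frame(
    id = c(adult_ids, off_ids), x = c(ax, ox), y = c(ay, oy),
    stage = c(rep("adult", na), rep("seedling", no)),
    reproductive = c(repro, rep(0, no)))
  list(samples = samples, genotypes = g_obs, genotypes_true = g_true,
       pedigree = if (no > 0) do.call(rbind, ped) else NULL, config = cfg)
}

#' Simulate an isolation-by-distance population at drift-dispersal equilibrium
#'
#' Non-overlapping generations of constant size on a toroidal arena: each
#' offspring picks a mother uniformly, a father with probability proportional
#' to a Gaussian kernel of the mother-father distance, and is placed at the
#' mother's position plus a Gaussian displacement. The per-axis seed and
#' pollen scales are both set to \code{sigma_true / sqrt(1.5)} so that the
#' axial gene-dispersal variance (averaged over the maternal and paternal
#' gamete paths) equals \code{sigma_true^2}. Genotypes propagate by Mendelian
#' inheritance from Hardy-Weinberg founders.
#'
#' @param sigma_true axial root-mean-squared gene-dispersal distance (m).
#' @param density individuals per hectare (constant; the effective density
#'   equals it under the Poisson-offspring mating scheme used).
#' @param n_generations generations simulated (>= 10 recommended for
#'   approach to equilibrium).
#' @param arena \code{c(width, height)} in metres (torus).
#' @param n_loci number of loci.
#' @param freq_range founder allele-frequency range.
#' @param seed integer seed.
#' @return List with \code{samples} (all individuals of the final
#'   generation), \code{genotypes}, \code{density_per_ha}, \code{arena} and
#'   \code{sigma_true}.
#' @export
simulate_ibd_population <- function(sigma_true, density, n_generations,
                                    arena, n_loci, freq_range = c(0.1, 0.9),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  area_ha <- prod(arena) / 1e4
  n <- round(density * area_ha)
  if (n < 10) stop("density x arena must give at least 10 individuals")
  if (n_generations < 1) stop("need at least one generation")
  s_axis <- sigma_true / sqrt(1.5)
  q <- stats::runif(n_loci, freq_range[1], freq_range[2])
  x <- stats::runif(n, 0, arena[1])
  y <- stats::runif(n, 0, arena[2])
  geno <- .hw_genotypes(n, q)
  wrap <- function(v, lim) ((v %% lim) + lim) %% lim
  for (gen in seq_len(n_generations)) {
    mothers <- sample.int(n, n, replace = TRUE)
    dx <- abs(outer(x[mothers], x, "-")); dx <- pmin(dx, arena[1] - dx)
    dy <- abs(outer(y[mothers], y, "-")); dy <- pmin(dy, arena[2] - dy)
    w <- exp(-(dx^2 + dy^2) / (2 * s_axis^2))
    w[cbind(seq_len(n), mothers)] <- 0        # no selfing
    fathers <- vapply(seq_len(n), function(k) {
      wk <- w[k, ]
      if (sum(wk) == 0) {
        dk <- dx[k, ]^2 + dy[k, ]^2
        dk[mothers[k]] <- Inf
        which.min(dk)
      } else sample.int(n, 1, prob = wk)
    }, 0L)
    nx <- wrap(x[mothers] + stats::rnorm(n, 0, s_axis), arena[1])
    ny <- wrap(y[mothers] + stats::rnorm(n, 0, s_axis), arena[2])
    geno <- .gamete(geno[mothers, , drop = FALSE]) +
      .gamete(geno[fathers, , drop = FALSE])
    x <- nx; y <- ny
  }
  ids <- sprintf("ibd_%04d", seq_len(n))
  rownames(geno) <- ids
  samples <- data.frame(id = ids, x = x, y = y, stage = "adult",
                        reproductive = 1)
  list(samples = samples, genotypes = genotype_matrix(geno),
       density_per_ha = n / area_ha, arena = arena, sigma_true = sigma_true)
}
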