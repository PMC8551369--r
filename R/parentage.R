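#' Configuration for likelihood-based parentage analysis
#'
#' @param error_rate per-genotype error rate e used in both the LOD error
#'   model and the Delta simulation (default 0.01).
#' @param prop_sampled probability that a true parent is among the sampled
#'   candidates (default 0.90).
#' @param n_sim number of simulated offspring for the Delta criterion
#'   (default 50,000; at least 1,000).
#' @param confidence assignment confidence level (default 0.95).
#' @param allow_selfing evaluate self-pairs (same candidate as both parents)?
#' @return Object of class \code{"parentage_config"}.
#' @export
parentage_config <- function(error_rate = 0.01, prop_sampled = 0.90,
                             n_sim = 50000, confidence = 0.95,
                             allow_selfing = TRUE) {
  stopifnot(error_rate >= 0, error_rate < 1,
            prop_sampled >= 0, prop_sampled <= 1,
            n_sim >= 1000, confidence > 0, confidence < 1)
  structure(list(error_rate = error_rate, prop_sampled = prop_sampled,
                 n_sim = n_sim, confidence = confidence,
                 allow_selfing = allow_selfing),
            class = "parentage_config")
}

#' Allele frequencies from a subset of individuals
#'
#' Reference (alternate) allele frequency per locus from the non-missing
#' genotypes of the chosen subset -- by default the reproductive adults, the
#' convention for parentage likelihoods. Loci with no data in the subset are
#' \code{NA} and skipped downstream; fixed loci are uninformative.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param individuals index (ids, logical or integer) of the subset; default
#'   all individuals.
#' @return Named numeric vector of alternate-allele frequencies.
#' @export
allele_frequencies <- function(g, individuals = NULL) {
  g <- as_genotype_matrix(g)
  if (is.null(individuals)) individuals <- seq_len(nrow(g))
  if (is.character(individuals)) individuals <- match(individuals, rownames(g))
  x <- unclass(g)[individuals, , drop = FALSE]
  if (nrow(x) == 0) stop("empty subset")
  n <- colSums(!is.na(x))
  q <- colSums(x, na.rm = TRUE) / (2 * n)
  q[n == 0] <- NA_real_
  q
}

#' Mendelian transmission probability with one unknown parent
#'
#' P(offspring genotype | one known parent, the other parent an unrelated
#' Hardy-Weinberg draw at alternate-allele frequency \code{p_alt}).
#'
#' @param g_offspring,g_parent dosage genotypes (0, 1, 2); vectorized.
#' @param p_alt alternate allele frequency.
#' @return Transmission probability.
#' @export
transition_prob <- function(g_offspring, g_parent, p_alt) {
  n <- max(length(g_offspring), length(g_parent), length(p_alt))
  go <- rep_len(g_offspring, n)
  u <- rep_len(g_parent, n) / 2
  q <- rep_len(p_alt, n)
  ifelse(go == 0, (1 - u) * (1 - q),
         ifelse(go == 1, u * (1 - q) + (1 - u) * q, u * q))
}

# Per-locus log likelihood-ratio lookup tables for the error model
#   observed = true with prob (1-e), random HW genotype with prob e
# lr1: 9 x L, index (g_parent * 3 + g_offspring) + 1
# lr2: 27 x L, index (g_p1 * 9 + g_p2 * 3 + g_offspring) + 1
# Only polymorphic loci with defined frequencies enter (others uninformative).
.lod_tables <- function(freqs, e) {
  use <- which(is.finite(freqs) & freqs > 0 & freqs < 1)
  q <- freqs[use]
  l <- length(q)
  if (l == 0) stop("no polymorphic locus with defined frequencies")
  p0 <- rbind((1 - q)^2, 2 * q * (1 - q), q^2)     # 3 x L
  gp <- 0:2
  t1 <- array(0, c(3, 3, l))                        # [parent, offspring, locus]
  for (a in gp) for (o in gp)
    t1[a + 1, o + 1, ] <- transition_prob(o, a, q)
  # layout matches the linear index conventions below: offspring genotype is
  # the fastest-varying dimension
  lr1 <- array(0, c(3, 3, l))                       # [offspring, parent, locus]
  k1 <- 1 - (1 - e)^2
  for (a in gp) for (o in gp)
    lr1[o + 1, a + 1, ] <- log((1 - e)^2 * t1[a + 1, o + 1, ] +
                                 k1 * p0[o + 1, ]) - log(p0[o + 1, ])
  lr2 <- array(0, c(3, 3, 3, l))                    # [offspring, p2, p1, locus]
  kp <- e + e^2 * (1 - e)
  for (a in gp) for (b in gp) {
    u <- a / 2; v <- b / 2
    t2 <- c((1 - u) * (1 - v), u * (1 - v) + (1 - u) * v, u * v)
    for (o in gp) {
      lr2[o + 1, b + 1, a + 1, ] <-
        log((1 - e)^3 * t2[o + 1] +
              e * (1 - e)^2 * (t1[a + 1, o + 1, ] + t1[b + 1, o + 1, ]) +
              kp * p0[o + 1, ]) - log(p0[o + 1, ])
    }
  }
  list(lr1 = matrix(lr1, 9, l), lr2 = matrix(lr2, 27, l),
       use = use, n_loci = l)
}

# sum of per-locus log LRs; NA indices (missing genotypes) contribute zero
.lod_lookup <- function(tabv, idx, n_row, n_loci) {
  vals <- matrix(tabv[idx], n_row, n_loci)
  vals[is.na(idx)] <- 0
  rowSums(vals)
}

#' Single-parent LOD score
#'
#' Natural-log likelihood ratio that the candidate is a parent of the
#' offspring versus unrelated, summed over loci where both are genotyped.
#' The error model replaces each observed genotype independently with a
#' random Hardy-Weinberg genotype at rate \code{e}; with \code{e = 0} a
#' single Mendelian incompatibility gives -Inf (hard exclusion).
#'
#' @param g_o,g_c offspring and candidate dosage vectors (NA = missing).
#' @param freqs alternate-allele frequencies (e.g.
#'   \code{\link{allele_frequencies}}).
#' @param e per-genotype error rate.
#' @return LOD score (NA if no shared genotyped locus).
#' @export
lod_single_parent <- function(g_o, g_c, freqs, e = 0.01) {
  tab <- .lod_tables(freqs, e)
  go <- g_o[tab$use]; gc <- g_c[tab$use]
  shared <- !is.na(go) & !is.na(gc)
  if (!any(shared)) return(NA_real_)
  idx <- (gc * 3 + go + 1) + 9 * (seq_along(go) - 1)
  sum(tab$lr1[idx[shared]])
}

#' Parent-pair LOD score
#'
#' LOD of the joint hypothesis that the two candidates (unordered; the same
#' id twice encodes selfing) are the offspring's parents versus both
#' unrelated. Loci enter when the offspring and both candidates are
#' genotyped. Per-locus LODs add across loci.
#'
#' @param g_o,g_c1,g_c2 dosage vectors.
#' @inheritParams lod_single_parent
#' @return LOD score.
#' @export
lod_parent_pair <- function(g_o, g_c1, g_c2, freqs, e = 0.01) {
  tab <- .lod_tables(freqs, e)
  go <- g_o[tab$use]; g1 <- g_c1[tab$use]; g2 <- g_c2[tab$use]
  shared <- !is.na(go) & !is.na(g1) & !is.na(g2)
  if (!any(shared)) return(NA_real_)
  idx <- (g1 * 9 + g2 * 3 + go + 1) + 27 * (seq_along(go) - 1)
  sum(tab$lr2[idx[shared]])
}

# CERVUS-style Delta: gap between the two highest LODs among candidates with
# positive LOD; equals the top LOD when it is the only positive one.
.delta_of <- function(lods) {
  top <- which.max(lods)
  npos <- sum(lods > 0)
  delta <- if (npos == 0) 0
  else if (npos == 1) lods[top]
  else {
    srt <- sort(lods, decreasing = TRUE)
    srt[1] - srt[2]
  }
  list(top = top, delta = delta, assignable = npos > 0)
}

# smallest threshold at which the success rate among simulated offspring with
# Delta above it reaches the confidence level
.delta_threshold <- function(delta, correct, confidence) {
  assigned <- delta > 0
  delta <- delta[assigned]; correct <- correct[assigned]
  if (!length(delta)) {
    warning("no assignable simulated offspring; Delta criterion unattainable")
    return(Inf)
  }
  ord <- order(delta, decreasing = TRUE)
  cum <- cumsum(correct[ord]) / seq_along(ord)
  ok <- which(cum >= confidence)
  if (!length(ok)) {
    warning("confidence level unattainable; Delta criterion set to +Inf")
    return(Inf)
  }
  k <- max(ok)
  if (k == length(ord)) 0 else delta[ord][k + 1]
}

#' Simulate the critical Delta for parentage assignment
#'
#' CERVUS-style simulation: offspring are generated from random
#' Hardy-Weinberg parent pairs at the supplied allele frequencies with
#' per-genotype error; each true parent is present among the candidates with
#' probability \code{prop_sampled}, the remaining candidates being unrelated.
#' Delta is computed for every simulated offspring (single-parent and
#' parent-pair analyses) and the critical values are the smallest thresholds
#' at which the proportion of correct assignments above them reaches the
#' configured confidence.
#'
#' @param freqs alternate-allele frequencies.
#' @param n_candidates number of candidate parents (>= 2).
#' @param cfg a \code{\link{parentage_config}}.
#' @param seed integer seed (the simulation is deterministic given it).
#' @return List of class \code{"delta_crit"}: \code{delta_single},
#'   \code{delta_pair}, assignment success rates at those thresholds and the
#'   simulated Delta samples.
#' @export
simulate_delta_crit <- function(freqs, n_candidates, cfg = parentage_config(),
                                seed = NULL) {
  stopifnot(n_candidates >= 2)
  if (!is.null(seed)) set.seed(seed)
  tab <- .lod_tables(freqs, cfg$error_rate)
  q <- freqs[tab$use]
  l <- tab$n_loci
  nc <- n_candidates
  lr1v <- as.vector(tab$lr1)
  lr2v <- as.vector(tab$lr2)
  off1 <- 9 * (seq_len(l) - 1) + 1
  off2 <- 27 * (seq_len(l) - 1) + 1
  pair_i <- pair_j <- integer(0)
  for (i in seq_len(nc)) {
    js <- if (cfg$allow_selfing) i:nc else if (i < nc) (i + 1):nc else integer(0)
    pair_i <- c(pair_i, rep(i, length(js)))
    pair_j <- c(pair_j, js)
  }
  np <- length(pair_i)
  gamete <- function(g) (g == 2) + (g == 1) * stats::rbinom(l, 1, 0.5)
  corrupt <- function(g) {
    err <- stats::runif(l) < cfg$error_rate
    if (any(err)) g[err] <- stats::rbinom(sum(err), 2, q[err])
    g
  }
  d_single <- d_pair <- numeric(cfg$n_sim)
  c_single <- c_pair <- logical(cfg$n_sim)
  for (s in seq_len(cfg$n_sim)) {
    gm <- stats::rbinom(l, 2, q)
    gf <- stats::rbinom(l, 2, q)
    go <- corrupt(gamete(gm) + gamete(gf))
    cand <- matrix(stats::rbinom(nc * l, 2, rep(q, each = nc)), nc, l)
    ms <- stats::runif(1) < cfg$prop_sampled
    fs <- stats::runif(1) < cfg$prop_sampled
    if (ms) cand[1, ] <- corrupt(gm)
    if (fs) cand[2, ] <- corrupt(gf)
    lods1 <- rowSums(matrix(lr1v[cand * 3 + rep(go + off1, each = nc)], nc, l))
    ds <- .delta_of(lods1)
    d_single[s] <- ds$delta
    c_single[s] <- ds$assignable &&
      ((ms && ds$top == 1L) || (fs && ds$top == 2L))
    lods2 <- rowSums(matrix(
      lr2v[cand[pair_i, , drop = FALSE] * 9 + cand[pair_j, , drop = FALSE] * 3 +
             rep(go + off2, each = np)], np, l))
    dp <- .delta_of(lods2)
    d_pair[s] <- dp$delta
    c_pair[s] <- dp$assignable && ms && fs &&
      pair_i[dp$top] == 1L && pair_j[dp$top] == 2L
  }
  structure(list(
    delta_single = .delta_threshold(d_single, c_single, cfg$confidence),
    delta_pair = .delta_threshold(d_pair, c_pair, cfg$confidence),
    success_single = mean(c_single), success_pair = mean(c_pair),
    d_single = d_single, d_pair = d_pair,
    confidence = cfg$confidence, n_sim = cfg$n_sim),
    class = "delta_crit")
}

#' @export
print.delta_crit <- function(x, ...) {
  cat(sprintf("delta_crit (%d simulations, %.0f%% confidence):\n",
              x$n_sim, 100 * x$confidence))
  cat(sprintf("  single parent: %.3f (raw success %.1f%%)\n",
              x$delta_single, 100 * x$success_single))
  cat(sprintf("  parent pair:   %.3f (raw success %.1f%%)\n",
              x$delta_pair, 100 * x$success_pair))
  invisible(x)
}

#' Assign parents to offspring by the Delta criterion
#'
#' Evaluates every single candidate and every unordered candidate pair
#' (including self-pairs when selfing is allowed) for each offspring. A pair
#' is assigned when its Delta exceeds the pair criterion; otherwise a single
#' parent is assigned when its Delta exceeds the single criterion; otherwise
#' no parent. With two distinct assigned parents the one nearer the offspring
#' is taken as maternal (seed dispersal) and the farther as paternal (pollen
#' dispersal); ties break by candidate id order. A lone assigned parent is
#' treated as maternal with immigrant pollen. Selfing is recorded when both
#' assigned parents are the same tree.
#'
#' @param g a \code{\link{genotype_matrix}} containing offspring and
#'   candidates.
#' @param samples sample map with coordinates for all individuals.
#' @param offspring_ids,candidate_ids identifier vectors (must not overlap).
#' @param freqs allele frequencies for the likelihoods (default: computed
#'   from the candidates).
#' @param cfg a \code{\link{parentage_config}}.
#' @param delta_crit a \code{\link{simulate_delta_crit}} result (or a list
#'   with \code{delta_single}, \code{delta_pair}).
#' @return Data frame of class \code{"parentage_assignments"}: one row per
#'   offspring with assigned ids, category (\code{both_parents},
#'   \code{single_parent}, \code{selfed}, \code{no_parent}), LODs, Deltas and
#'   seed/pollen dispersal distances (m).
#' @export
assign_parentage <- function(g, samples, offspring_ids, candidate_ids,
                             freqs = NULL, cfg = parentage_config(),
                             delta_crit) {
  g <- as_genotype_matrix(g)
  if (length(intersect(offspring_ids, candidate_ids)))
    stop("offspring also present in candidate list")
  x <- unclass(g)
  if (is.null(freqs)) freqs <- allele_frequencies(g, candidate_ids)
  tab <- .lod_tables(freqs, cfg$error_rate)
  l <- tab$n_loci
  lr1v <- as.vector(tab$lr1); lr2v <- as.vector(tab$lr2)
  off1 <- 9 * (seq_len(l) - 1) + 1
  off2 <- 27 * (seq_len(l) - 1) + 1
  cand <- x[candidate_ids, tab$use, drop = FALSE]
  nc <- length(candidate_ids)
  pair_i <- pair_j <- integer(0)
  for (i in seq_len(nc)) {
    js <- if (cfg$allow_selfing) i:nc else if (i < nc) (i + 1):nc else integer(0)
    pair_i <- c(pair_i, rep(i, length(js)))
    pair_j <- c(pair_j, js)
  }
  np <- length(pair_i)
  dmat <- pairwise_distances(samples)

  res <- vector("list", length(offspring_ids))
  for (k in seq_along(offspring_ids)) {
    oid <- offspring_ids[k]
    go <- x[oid, tab$use]
    idx1 <- cand * 3 + rep(go + off1, each = nc)
    lods1 <- .lod_lookup(lr1v, idx1, nc, l)
    idx2 <- cand[pair_i, , drop = FALSE] * 9 +
      cand[pair_j, , drop = FALSE] * 3 + rep(go + off2, each = np)
    lods2 <- .lod_lookup(lr2v, idx2, np, l)
    ds <- .delta_of(lods1)
    dp <- .delta_of(lods2)

    maternal <- paternal <- NA_character_
    category <- "no_parent"
    seed_d <- pollen_d <- NA_real_
    if (dp$assignable && dp$delta > delta_crit$delta_pair) {
      a <- candidate_ids[pair_i[dp$top]]
      b <- candidate_ids[pair_j[dp$top]]
      if (a == b) {
        maternal <- paternal <- a
        category <- "selfed"
        seed_d <- dmat[oid, a]
      } else {
        da <- dmat[oid, a]; db <- dmat[oid, b]
        # nearer parent is maternal; exact ties resolved by id sort order
        nearer_a <- da < db || (da == db && a < b)
        maternal <- if (nearer_a) a else b
        paternal <- if (nearer_a) b else a
        category <- "both_parents"
        seed_d <- min(da, db); pollen_d <- max(da, db)
      }
    } else if (ds$assignable && ds$delta > delta_crit$delta_single) {
      maternal <- candidate_ids[ds$top]
      category <- "single_parent"
      seed_d <- dmat[oid, maternal]
    }
    res[[k]] <- data.frame(
      offspring_id = oid, maternal_id = maternal, paternal_id = paternal,
      category = category, seed_distance_m = seed_d,
      pollen_distance_m = pollen_d,
      lod_single = lods1[ds$top], delta_single = ds$delta,
      lod_pair = lods2[dp$top], delta_pair = dp$delta)
  }
  out <- do.call(rbind, res)
  class(out) <- c("parentage_assignments", "data.frame")
  out
}

#' Combined parent-pair non-exclusion probability
#'
#' Per-locus probability that a random unrelated candidate pair is Mendelian-
#' compatible with a random offspring of the population (all genotypes drawn
#' under Hardy-Weinberg at the supplied frequencies), combined as the product
#' across loci. Monomorphic loci contribute 1 (uninformative). Returned on
#' the natural scale together with its log10, since products over thousands
#' of SNPs underflow.
#'
#' @param freqs alternate-allele frequencies.
#' @return List with \code{p_p}, \code{log10_p_p} and the per-locus vector.
#' @export
non_exclusion_pp <- function(freqs) {
  use <- is.finite(freqs) & freqs > 0 & freqs < 1
  if (!any(use)) return(list(p_p = 1, log10_p_p = 0, per_locus = numeric(0)))
  q <- freqs[use]
  per <- vapply(q, function(qq) {
    p0 <- c((1 - qq)^2, 2 * qq * (1 - qq), qq^2)
    tot <- 0
    for (a in 0:2) for (b in 0:2) {
      u <- a / 2; v <- b / 2
      t2 <- c((1 - u) * (1 - v), u * (1 - v) + (1 - u) * v, u * v)
      compatible <- t2 > 0
      tot <- tot + p0[a + 1] * p0[b + 1] * sum(p0[compatible])
    }
    tot
  }, 0)
  lg <- sum(log10(per))
  list(p_p = 10^lg, log10_p_p = lg, per_locus = per)
}

#' Cryptic gene flow probability
#'
#' Probability that at least one of \code{n} unrelated in-population
#' candidates escapes exclusion when the true parent is outside the sampled
#' area: \eqn{C_{gf} = 1 - (1 - P_p)^n}.
#'
#' @param p_p combined parent-pair non-exclusion probability in [0, 1].
#' @param n number of candidate parents (>= 1).
#' @return C_gf in [0, 1].
#' @export
cryptic_gene_flow <- function(p_p, n) {
  stopifnot(p_p >= 0, p_p <= 1, n >= 1)
  -expm1(n * log1p(-p_p))
}

#' Summarize dispersal from parentage assignments
#'
#' Seed immigration m_s is the fraction of offspring with no assigned parent;
#' pollen immigration m_p the fraction with a single assigned parent. Seed
#' dispersal distances are offspring-to-maternal distances (all offspring
#' with a maternal assignment); pollen dispersal distances are offspring-to-
#' paternal distances of two-distinct-parent offspring. The total direct
#' gene-flow distance is \eqn{\sigma_{rt} = \sqrt{\frac{1}{2}\sigma^2_p +
#' \sigma^2_s}} with sample (n-1) variances of the two distance sets.
#'
#' @param assignments a \code{\link{assign_parentage}} /
#'   \code{\link{classify_assignments}} result.
#' @return List of class \code{"dispersal_summary"}: \code{m_s}, \code{m_p},
#'   \code{selfing_rate}, \code{seed_distances}, \code{pollen_distances},
#'   \code{sigma_rt} (NA with a flag when fewer than two distances of either
#'   kind are available).
#' @export
dispersal_summary <- function(assignments) {
  a <- assignments
  n <- nrow(a)
  seed_d <- a$seed_distance_m[!is.na(a$seed_distance_m)]
  pollen_d <- a$pollen_distance_m[a$category == "both_parents" &
                                    !is.na(a$pollen_distance_m)]
  sigma_rt <- if (length(seed_d) >= 2 && length(pollen_d) >= 2)
    sqrt(0.5 * stats::var(pollen_d) + stats::var(seed_d)) else NA_real_
  structure(list(
    m_s = sum(a$category == "no_parent") / n,
    m_p = sum(a$category == "single_parent") / n,
    selfing_rate = sum(a$category == "selfed") / n,
    seed_distances = seed_d, pollen_distances = pollen_d,
    sigma_rt = sigma_rt, n_offspring = n),
    class = "dispersal_summary")
}

#' @export
print.dispersal_summary <- function(x, ...) {
  cat(sprintf("dispersal_summary (%d offspring):\n", x$n_offspring))
  cat(sprintf("  seed immigration m_s = %.4f, pollen immigration m_p = %.4f, selfing = %.4f\n",
              x$m_s, x$m_p, x$selfing_rate))
  if (length(x$seed_distances))
    cat(sprintf("  seed distances: mean %.1f m (n = %d)\n",
                mean(x$seed_distances), length(x$seed_distances)))
  if (length(x$pollen_distances))
    cat(sprintf("  pollen distances: mean %.1f m (n = %d)\n",
                mean(x$pollen_distances), length(x$pollen_distances)))
  cat(sprintf("  sigma_rt = %.1f m\n", x$sigma_rt))
  invisible(x)
}

#' Category counts from parentage assignments
#'
#' @param assignments an assignments data frame.
#' @return List with the category counts, selfing rate and the numbers of
#'   distinct maternal, paternal and overall parental trees.
#' @export
parentage_counts <- function(assignments) {
  a <- assignments
  mat <- a$maternal_id[!is.na(a$maternal_id)]
  pat <- a$paternal_id[!is.na(a$paternal_id)]
  list(n_offspring = nrow(a),
       n_both_parents = sum(a$category %in% c("both_parents", "selfed")),
       n_selfed = sum(a$category == "selfed"),
       n_single_parent = sum(a$category == "single_parent"),
       n_no_parent = sum(a$category == "no_parent"),
       selfing_rate = sum(a$category == "selfed") / nrow(a),
       n_maternal_trees = length(unique(mat)),
       n_paternal_trees = length(unique(pat)),
       n_parental_trees = length(unique(c(mat, pat))))
}

#' Classify a per-offspring candidate table into parentage assignments
#'
#' Applies the assignment bookkeeping to a table of top candidates per
#' offspring, as published parentage outputs are laid out: two candidate
#' parents with LOD significance flags, a maternal flag on the nearer parent,
#' and a pair-LOD significance flag. A significant pair gives both parents
#' (selfed when the ids coincide); otherwise the one significant candidate is
#' a lone maternal parent; otherwise no parent.
#'
#' @param tab data frame with columns \code{offspring_id}, \code{parent1_id},
#'   \code{parent1_sig}, \code{parent1_maternal}, \code{parent2_id},
#'   \code{parent2_sig}, \code{parent2_maternal}, \code{pair_sig}.
#' @param samples optional sample map; when given, seed and pollen distances
#'   are filled in from the coordinates.
#' @return A \code{parentage_assignments} data frame (see
#'   \code{\link{assign_parentage}}).
#' @export
classify_assignments <- function(tab, samples = NULL) {
  need <- c("offspring_id", "parent1_id", "parent1_sig", "parent1_maternal",
            "parent2_id", "parent2_sig", "parent2_maternal", "pair_sig")
  stopifnot(all(need %in% names(tab)))
  dmat <- if (!is.null(samples)) pairwise_distances(samples)
  rows <- lapply(seq_len(nrow(tab)), function(k) {
    r <- tab[k, ]
    maternal <- paternal <- NA_character_
    category <- "no_parent"
    seed_d <- pollen_d <- NA_real_
    if (isTRUE(as.logical(r$pair_sig))) {
      if (r$parent1_id == r$parent2_id) {
        maternal <- paternal <- r$parent1_id
        category <- "selfed"
      } else {
        maternal <- if (isTRUE(as.logical(r$parent1_maternal)))
          r$parent1_id else r$parent2_id
        paternal <- setdiff(c(r$parent1_id, r$parent2_id), maternal)
        category <- "both_parents"
      }
    } else {
      sig <- c(as.logical(r$parent1_sig), as.logical(r$parent2_sig))
      if (any(sig)) {
        maternal <- c(r$parent1_id, r$parent2_id)[which(sig)[1]]
        category <- "single_parent"
      }
    }
    if (!is.null(dmat) && !is.na(maternal))
      seed_d <- dmat[r$offspring_id, maternal]
    if (!is.null(dmat) && category == "both_parents")
      pollen_d <- dmat[r$offspring_id, paternal]
    data.frame(offspring_id = r$offspring_id, maternal_id = maternal,
               paternal_id = paternal, category = category,
               seed_distance_m = seed_d, pollen_distance_m = pollen_d,
               lod_single = NA_real_, delta_single = NA_real_,
               lod_pair = NA_real_, delta_pair = NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("parentage_assignments", "data.frame")
  out
}

#' Full likelihood-based parentage analysis
#'
#' The direct-gene-flow entry point: takes genotypes plus a sample map,
#' treats seedlings as offspring and reproductive adults as candidate
#' parents, estimates allele frequencies from the candidates, simulates the
#' Delta criteria, assigns parentage, and summarizes dispersal, the combined
#' parent-pair non-exclusion probability and cryptic gene flow.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param samples sample map (see \code{\link{read_sample_table}}).
#' @param cfg a \code{\link{parentage_config}}.
#' @param seed integer seed for the Delta simulation.
#' @return Object of class \code{"parentage"} with the assignments table,
#'   the Delta criteria, the dispersal summary, \code{p_p}, \code{c_gf} and
#'   bookkeeping counts.
#' @export
parentage <- function(g, samples, cfg = parentage_config(), seed = NULL) {
  g <- as_genotype_matrix(g)
  samples <- validate_sample_table(samples)
  offspring <- samples$id[samples$stage == "seedling"]
  candidates <- samples$id[samples$reproductive == 1]
  if (length(offspring) == 0) stop("no seedlings in the sample map")
  if (length(candidates) < 2) stop("need at least two candidate parents")
  freqs <- allele_frequencies(g, candidates)
  dc <- simulate_delta_crit(freqs, length(candidates), cfg, seed)
  asg <- assign_parentage(g, samples, offspring, candidates, freqs, cfg, dc)
  ne <- non_exclusion_pp(freqs)
  structure(list(assignments = asg, delta_crit = dc,
                 dispersal = dispersal_summary(asg),
                 counts = parentage_counts(asg),
                 p_p = ne$p_p, log10_p_p = ne$log10_p_p,
                 c_gf = cryptic_gene_flow(ne$p_p, length(candidates)),
                 n_candidates = length(candidates), cfg = cfg),
            class = "parentage")
}

#' @export
print.parentage <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("Parentage analysis: %d offspring, %d candidate parents\n",
              ct$n_offspring, x$n_candidates))
  cat(sprintf("  both parents: %d (of which selfed: %d)   single parent: %d   none: %d\n",
              ct$n_both_parents, ct$n_selfed, ct$n_single_parent,
              ct$n_no_parent))
  cat(sprintf("  selfing rate s = %.3f   m_p = %.4f   m_s = %.4f\n",
              ct$selfing_rate, x$dispersal$m_p, x$dispersal$m_s))
  cat(sprintf("  parent-pair non-exclusion log10(P_p) = %.1f; cryptic gene flow C_gf = %.3g\n",
              x$log10_p_p, x$c_gf))
  if (!is.na(x$dispersal$sigma_rt))
    cat(sprintf("  direct gene-flow distance sigma_rt = %.1f m\n",
                x$dispersal$sigma_rt))
  invisible(x)
}

#' @export
summary.parentage <- function(object, ...) {
  print(object)
  cat("\nAssignments:\n")
  print(as.data.frame(object$assignments)[, 1:6], row.names = FALSE)
  invisible(object)
}
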