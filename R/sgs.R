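#' Pairwise Euclidean distances from a sample map
#'
#' Symmetric distance matrix (metres) from planar coordinates. With
#' \code{arena} set, distances are computed on a torus of those dimensions
#' (minimal-image convention), matching the geometry of the
#' isolation-by-distance simulator. Distinct individuals at identical
#' coordinates yield distance zero and are flagged via the
#' \code{zero_distance_pairs} attribute.
#'
#' @param samples a sample map data frame (see \code{\link{read_sample_table}})
#'   or any data frame with \code{id}, \code{x}, \code{y}.
#' @param arena optional \code{c(width, height)} of a toroidal arena (m).
#' @return Distance matrix with individual ids as dimnames.
#' @export
pairwise_distances <- function(samples, arena = NULL) {
  if (!all(c("id", "x", "y") %in% names(samples)))
    stop("samples must have columns id, x, y")
  bad <- !is.finite(samples$x) | !is.finite(samples$y)
  if (any(bad))
    stop("missing coordinates for: ", paste(samples$id[bad], collapse = ", "))
  dx <- abs(outer(samples$x, samples$x, "-"))
  dy <- abs(outer(samples$y, samples$y, "-"))
  if (!is.null(arena)) {
    dx <- pmin(dx, arena[1] - dx)
    dy <- pmin(dy, arena[2] - dy)
  }
  d <- sqrt(dx^2 + dy^2)
  dimnames(d) <- list(samples$id, samples$id)
  zero <- which(upper.tri(d) & d == 0, arr.ind = TRUE)
  attr(d, "zero_distance_pairs") <-
    if (nrow(zero)) cbind(samples$id[zero[, 1]], samples$id[zero[, 2]])
  d
}

#' Equal-pair-count distance classes
#'
#' Partitions the pairwise distances into \code{k} classes holding equal
#' numbers of pairs (within one; ties are assigned deterministically by rank
#' order), the classing that maximizes the number of pairs per class. Explicit
#' upper bounds may be supplied instead to mimic a published classing.
#'
#' @param distances numeric vector of pairwise distances.
#' @param k number of classes (>= 2).
#' @param breaks optional vector of class upper bounds (last must cover the
#'   maximum distance); overrides \code{k}.
#' @return List with \code{class} (class index per pair), \code{bounds}
#'   (data frame class, lower, upper, n_pairs).
#' @export
make_distance_classes <- function(distances, k = 6, breaks = NULL) {
  d <- as.numeric(distances)
  if (!is.null(breaks)) {
    if (max(d) > max(breaks)) stop("breaks do not cover the maximum distance")
    cl <- findInterval(d, c(-Inf, breaks), left.open = TRUE)
  } else {
    if (k < 2) stop("k must be at least 2")
    if (length(unique(d)) < k) stop("fewer distinct distances than classes")
    r <- rank(d, ties.method = "first")
    cl <- ceiling(r * k / length(d))
  }
  kk <- max(cl)
  bounds <- data.frame(
    class = seq_len(kk),
    lower = vapply(seq_len(kk), function(c) min(d[cl == c], Inf), 0),
    upper = vapply(seq_len(kk), function(c) max(d[cl == c], -Inf), 0),
    n_pairs = as.vector(table(factor(cl, levels = seq_len(kk)))))
  list(class = cl, bounds = bounds)
}

#' Kinship-on-log-distance regression
#'
#' Ordinary least squares of pairwise kinship on the natural log of pairwise
#' distance over all distinct pairs (no class averaging). Pairs at distance
#' zero are excluded from the regression but join the first distance class for
#' the per-class means. F1 is the mean kinship in the first class.
#'
#' @param kin a \code{kinship_matrix} (see \code{\link{kinship-estimators}}).
#' @param distances distance matrix from \code{\link{pairwise_distances}}.
#' @param n_classes number of distance classes.
#' @param class_breaks optional explicit class upper bounds.
#' @return List with \code{b} (slope), \code{r_squared}, \code{f1},
#'   \code{classes} (per-class table with pair counts and mean kinship,
#'   plus jackknife SE/CI when the kinship object retains per-locus parts),
#'   \code{pairs} (data frame of pair values used), and jackknife SEs for
#'   \code{b} and \code{f1} when available.
#' @export
sgs_regression <- function(kin, distances, n_classes = 6,
                           class_breaks = NULL) {
  stopifnot(inherits(kin, "kinship_matrix"))
  ids <- kin$ids
  d <- distances[ids, ids]
  pi <- .pair_index(length(ids))
  kv <- kin$values[cbind(pi$i, pi$j)]
  dv <- d[cbind(pi$i, pi$j)]
  ok <- !is.na(kv)
  kv <- kv[ok]; dv <- dv[ok]
  if (sum(dv > 0) < 3) stop("need at least 3 pairs at positive distance")

  dc <- make_distance_classes(dv, k = n_classes, breaks = class_breaks)
  cl <- dc$class
  class_mean <- tapply(kv, cl, mean)
  f1 <- unname(class_mean[1])

  reg <- dv > 0
  ld <- log(dv[reg])
  kr <- kv[reg]
  ss <- sum((ld - mean(ld))^2)
  b <- sum((ld - mean(ld)) * (kr - mean(kr))) / ss
  r2 <- if (stats::sd(kr) > 0) stats::cor(ld, kr)^2 else NA_real_

  out <- list(b = b, r_squared = r2, f1 = f1,
              classes = cbind(dc$bounds,
                              mean_kinship = as.numeric(class_mean)),
              pairs = data.frame(i = ids[pi$i][ok], j = ids[pi$j][ok],
                                 distance = dv, kinship = kv, class = cl),
              n_zero_distance = sum(dv == 0))

  if (!is.null(kin$num_parts)) {
    sel <- which(ok)
    np <- kin$num_parts[sel, , drop = FALSE]
    dp <- kin$den_parts[sel, , drop = FALSE]
    l <- ncol(np)
    num <- rowSums(np); den <- rowSums(dp)
    # leave-one-locus-out pair values; a pair whose only shared locus is the
    # deleted one keeps its overall value (its pseudo-value is undefined)
    v <- (num - np) / (den - dp)
    bad <- !is.finite(v)
    if (any(bad)) v[bad] <- (num / den)[row(v)[bad]]
    ind <- outer(cl, sort(unique(cl)), "==") * 1
    cm <- crossprod(ind, v) / colSums(ind)          # class x locus means
    jk_se <- function(th) sqrt((l - 1) / l * rowSums((th - rowMeans(th))^2))
    class_se <- jk_se(cm)
    w <- rep(0, length(cl)); w[reg] <- (ld - mean(ld)) / ss
    b_l <- as.vector(crossprod(v, w))
    # recentre: slope pseudo-values need the permuted-out mean term; since
    # sum(w) = 0 the intercept term cancels and crossprod is the slope
    b_se <- sqrt((l - 1) / l * sum((b_l - mean(b_l))^2))
    f1_l <- cm[1, ]
    out$jackknife <- list(b_loo = b_l, f1_loo = f1_l, n_loci = l)
    out$b_se <- b_se
    out$f1_se <- class_se[1]
    out$classes$se <- as.numeric(class_se)
    out$classes$ci_lo <- out$classes$mean_kinship - 1.96 * class_se
    out$classes$ci_hi <- out$classes$mean_kinship + 1.96 * class_se
  }
  out
}

#' Permutation test for spatial genetic structure
#'
#' Permutes individual locations among individuals (equivalent to permuting
#' multilocus genotypes among coordinates), recomputes the
#' kinship-on-log-distance slope each time, and returns the two-tailed
#' p-value \eqn{(r + 1)/(n_{perm} + 1)} where r counts permuted |b| at least
#' as large as observed.
#'
#' @param kin a \code{kinship_matrix}.
#' @param distances distance matrix.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional integer seed for reproducibility.
#' @return List with \code{p}, \code{b_obs} and the permuted slopes
#'   \code{b_perm}.
#' @export
permutation_test <- function(kin, distances, n_perm = 10000, seed = NULL) {
  stopifnot(inherits(kin, "kinship_matrix"))
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  ids <- kin$ids
  n <- length(ids)
  d <- distances[ids, ids]
  pi <- .pair_index(n)
  kv <- kin$values[cbind(pi$i, pi$j)]
  ok <- !is.na(kv)
  slope <- function(dv) {
    sel <- ok & dv > 0
    ld <- log(dv[sel]); kr <- kv[sel]
    sum((ld - mean(ld)) * (kr - mean(kr))) / sum((ld - mean(ld))^2)
  }
  b_obs <- slope(d[cbind(pi$i, pi$j)])
  b_perm <- vapply(seq_len(n_perm), function(r) {
    idx <- sample.int(n)
    slope(d[cbind(idx[pi$i], idx[pi$j])])
  }, 0)
  list(p = (sum(abs(b_perm) >= abs(b_obs)) + 1) / (n_perm + 1),
       b_obs = b_obs, b_perm = b_perm)
}

#' Sp statistic of SGS intensity
#'
#' \eqn{Sp = -b / (1 - F_1)}: the regression slope of pairwise kinship on
#' log distance scaled by the mean kinship of the first distance class.
#'
#' @param b regression slope.
#' @param f1 mean first-class kinship (must be < 1).
#' @return Sp.
#' @export
sp_statistic <- function(b, f1) {
  if (any(f1 >= 1)) stop("f1 must be below 1")
  -b / (1 - f1)
}

#' Wright's neighborhood size from Sp
#'
#' Nb = 1/Sp; defined only for positive Sp (positive SGS). A confidence
#' interval for Sp propagates to Nb by taking reciprocals of the interval
#' endpoints (monotone transform).
#'
#' @param sp Sp statistic (> 0).
#' @param sp_ci optional length-2 CI for Sp.
#' @return Nb, with attribute \code{ci} when \code{sp_ci} is supplied.
#' @export
neighborhood_size <- function(sp, sp_ci = NULL) {
  if (any(sp <= 0)) stop("neighborhood size undefined for Sp <= 0 (no positive SGS)")
  nb <- 1 / sp
  if (!is.null(sp_ci)) {
    if (any(sp_ci <= 0)) {
      attr(nb, "ci") <- c(NA_real_, NA_real_)
    } else {
      attr(nb, "ci") <- sort(1 / sp_ci)
    }
  }
  nb
}

#' Effective population density
#'
#' De = D x (Ne/N): census density scaled by the effective-to-census
#' population size ratio.
#'
#' @param d_census census density, individuals per hectare.
#' @param ne_over_n Ne/N ratio in (0, 1].
#' @return Object of class \code{"density_model"} with the census density, the
#'   ratio, \code{effective_density_de} (ind/ha) and \code{de_per_m2}.
#' @export
effective_density <- function(d_census, ne_over_n) {
  stopifnot(d_census > 0, ne_over_n > 0, ne_over_n <= 1)
  de <- d_census * ne_over_n
  structure(list(census_density_d = d_census, ne_over_n = ne_over_n,
                 effective_density_de = de, de_per_m2 = de / 1e4),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("density_model: D = %.3f ind/ha x Ne/N = %.2f -> De = %.3f ind/ha\n",
              x$census_density_d, x$ne_over_n, x$effective_density_de))
  invisible(x)
}

#' Indirect gene dispersal distance from neighborhood size
#'
#' At drift-dispersal equilibrium in two dimensions, Nb = 4 pi De sigma^2, so
#' sigma = sqrt(Nb / (4 pi De)) with De in individuals per square metre.
#'
#' @param nb neighborhood size (> 0).
#' @param de a \code{\link{effective_density}} model, or a numeric effective
#'   density in individuals per hectare.
#' @param nb_ci optional CI for Nb, propagated through the monotone transform.
#' @return sigma in metres, with attribute \code{ci} when \code{nb_ci} given.
#' @export
dispersal_sigma <- function(nb, de, nb_ci = NULL) {
  de_m2 <- if (inherits(de, "density_model")) de$de_per_m2 else de / 1e4
  stopifnot(nb > 0, de_m2 > 0)
  sig <- sqrt(nb / (4 * pi * de_m2))
  if (!is.null(nb_ci)) {
    attr(sig, "ci") <- sort(sqrt(nb_ci / (4 * pi * de_m2)))
  }
  sig
}

#' Fit a fine-scale spatial genetic structure model
#'
#' The main indirect-gene-flow entry point: computes pairwise kinship with the
#' chosen estimator, regresses it on log distance, summarizes per-distance-
#' class kinship with jackknife-across-loci confidence intervals, tests the
#' slope by permutation of locations, and derives the Sp statistic,
#' neighborhood size and (when a density is supplied) the indirect dispersal
#' distance sigma. Queller-Goodnight relationship values are converted to the
#' kinship scale via R = 2F/(1+F_I) using the sample inbreeding estimate
#' before the regression.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param samples sample map data frame (id, x, y, ...); rows are matched to
#'   the genotyped individuals by id.
#' @param estimator one of \code{"loiselle"}, \code{"ritland"},
#'   \code{"queller_goodnight"}.
#' @param n_classes number of equal-pair-count distance classes.
#' @param class_breaks optional explicit class upper bounds (m).
#' @param n_perm permutations for the slope test (0 skips the test).
#' @param census_density,ne_ratio census density (ind/ha) and Ne/N ratio for
#'   the effective-density model; both required for sigma.
#' @param distances optional precomputed distance matrix (e.g. toroidal).
#' @param jackknife retain per-locus parts for jackknife CIs.
#' @param seed integer seed for the permutation test.
#' @return An object of class \code{"sgs"}.
#' @export
sgs <- function(g, samples, estimator = c("loiselle", "ritland",
                                          "queller_goodnight"),
                n_classes = 6, class_breaks = NULL, n_perm = 10000,
                census_density = NULL, ne_ratio = NULL, distances = NULL,
                jackknife = TRUE, seed = NULL) {
  estimator <- match.arg(estimator)
  g <- as_genotype_matrix(g)
  samples <- samples[match(rownames(g), samples$id), , drop = FALSE]
  if (anyNA(samples$id)) stop("sample map lacks some genotyped individuals")
  if (is.null(distances)) distances <- pairwise_distances(samples)

  est_fun <- switch(estimator, loiselle = loiselle_kinship,
                    ritland = ritland_kinship,
                    queller_goodnight = queller_goodnight)
  kin <- est_fun(g, keep_parts = jackknife)
  fi <- NA_real_
  if (estimator == "queller_goodnight") {
    # convert relationship to kinship before the regression
    fi <- inbreeding(g)$mean_f
    kin$values <- r_to_f(kin$values, f_i = fi)
    if (!is.null(kin$num_parts))
      kin$num_parts <- kin$num_parts * (1 + fi) / 2
  }

  reg <- sgs_regression(kin, distances, n_classes = n_classes,
                        class_breaks = class_breaks)
  sp <- sp_statistic(reg$b, reg$f1)

  perm <- NULL
  if (n_perm > 0) perm <- permutation_test(kin, distances, n_perm, seed)

  sp_ci <- NULL
  if (!is.null(reg$jackknife)) {
    l <- reg$jackknife$n_loci
    sp_l <- sp_statistic(reg$jackknife$b_loo, reg$jackknife$f1_loo)
    sp_se <- sqrt((l - 1) / l * sum((sp_l - mean(sp_l))^2))
    sp_ci <- sp + c(-1.96, 1.96) * sp_se
  }

  nb <- nb_ci <- sigma <- sigma_ci <- de <- NULL
  if (sp > 0) {
    nb <- neighborhood_size(sp, sp_ci)
    nb_ci <- attr(nb, "ci"); attributes(nb) <- NULL
    if (!is.null(census_density) && !is.null(ne_ratio)) {
      de <- effective_density(census_density, ne_ratio)
      sigma <- dispersal_sigma(nb, de, nb_ci)
      sigma_ci <- attr(sigma, "ci"); attributes(sigma) <- NULL
    }
  }

  structure(list(estimator = estimator, kinship = kin, f_i = fi,
                 f1 = reg$f1, f1_se = reg$f1_se, b = reg$b, b_se = reg$b_se,
                 r_squared = reg$r_squared, classes = reg$classes,
                 pairs = reg$pairs, n_zero_distance = reg$n_zero_distance,
                 sp = sp, sp_ci = sp_ci,
                 p_perm = if (!is.null(perm)) perm$p else NA_real_,
                 n_perm = n_perm, nb = nb, nb_ci = nb_ci,
                 density = de, sigma_m = sigma, sigma_ci = sigma_ci,
                 n_individuals = nrow(g), n_loci = length(kin$loci)),
            class = "sgs")
}

#' @export
print.sgs <- function(x, ...) {
  cat(sprintf("Fine-scale SGS fit (%s estimator): %d individuals, %d loci\n",
              x$estimator, x$n_individuals, x$n_loci))
  cat(sprintf("  F1 = %.4f   b = %.5f   R^2 = %.3f   Sp = %.4f\n",
              x$f1, x$b, x$r_squared, x$sp))
  if (!is.na(x$p_perm))
    cat(sprintf("  permutation p (slope, %d perms) = %.4g\n",
                x$n_perm, x$p_perm))
  if (!is.null(x$nb))
    cat(sprintf("  neighborhood size Nb = %.2f%s\n", x$nb,
                if (!is.null(x$nb_ci)) sprintf(" (95%% CI %.2f-%.2f)",
                                               x$nb_ci[1], x$nb_ci[2]) else ""))
  if (!is.null(x$sigma_m))
    cat(sprintf("  indirect dispersal sigma = %.1f m%s\n", x$sigma_m,
                if (!is.null(x$sigma_ci)) sprintf(" (95%% CI %.1f-%.1f)",
                                                  x$sigma_ci[1], x$sigma_ci[2])
                else ""))
  invisible(x)
}

#' @export
summary.sgs <- function(object, ...) {
  print(object)
  cat("\nDistance classes:\n")
  print(object$classes, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.sgs <- function(object, ...) {
  c(f1 = object$f1, b = object$b, r_squared = object$r_squared,
    sp = object$sp, nb = if (is.null(object$nb)) NA_real_ else object$nb,
    sigma_m = if (is.null(object$sigma_m)) NA_real_ else object$sigma_m)
}

#' Kinship correlogram
#'
#' Per-distance-class mean kinship against class midpoint distance with
#' jackknife 95% confidence bars and a dashed zero line.
#'
#' @param x an \code{"sgs"} fit.
#' @param ... passed to \code{plot.default}.
#' @export
plot.sgs <- function(x, ...) {
  cl <- x$classes
  mid <- (cl$lower + cl$upper) / 2
  has_ci <- !is.null(cl$ci_lo)
  ylim <- range(c(cl$mean_kinship, if (has_ci) c(cl$ci_lo, cl$ci_hi), 0))
  graphics::plot(mid, cl$mean_kinship, type = "b", pch = 19,
                 xlab = "distance class midpoint (m)",
                 ylab = sprintf("mean kinship (%s)", x$estimator),
                 ylim = ylim, ...)
  if (has_ci)
    graphics::arrows(mid, cl$ci_lo, mid, cl$ci_hi, angle = 90, code = 3,
                     length = 0.04)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
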