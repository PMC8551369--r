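#' Pairwise kinship and relatedness estimators
#'
#' Multilocus pairwise estimators for biallelic SNP data:
#' \code{loiselle_kinship} and \code{ritland_kinship} estimate the kinship
#' (co-ancestry) coefficient F_ij, \code{queller_goodnight} the relationship
#' coefficient R_ij (about twice the kinship for non-inbred pairs). All three
#' combine loci as a ratio of sums (sum of per-locus numerators over sum of
#' per-locus denominators, restricted to loci where both pair members are
#' genotyped), the convention of the standard spatial-genetics software.
#' Reference allele frequencies are computed from the full analysis group --
#' including the focal pair -- unless \code{freq_individuals} narrows the
#' frequency sample.
#'
#' For the Loiselle estimator each locus contributes numerator
#' \eqn{(x_i - p)(x_j - p) + p(1-p)/(N_l - 1)} and denominator \eqn{p(1-p)},
#' where \eqn{x} is the individual allele fraction (dosage/2), \eqn{p} the
#' reference-group allele frequency and \eqn{N_l} the number of
#' frequency-group individuals genotyped at the locus; the small positive term
#' offsets the sampling covariance between an individual and the allele
#' frequency estimated from a sample containing it. The Ritland estimator
#' contributes \eqn{S_l = \sum_a x_{ia} x_{ja} / p_a - 1} with unit
#' denominator per locus; it is downward biased when very rare alleles are
#' present. The Queller-Goodnight estimator averages the two directional
#' forms by summing their numerators and denominators.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param freq_individuals optional index (names, logical or integer) of the
#'   individuals used to estimate allele frequencies; default all.
#' @param keep_parts retain per-locus pair numerators/denominators for
#'   jackknife-across-loci uncertainty (memory: 2 x pairs x loci doubles).
#' @return An object of class \code{"kinship_matrix"}: list with
#'   \code{estimator}, \code{values} (symmetric individual x individual
#'   matrix, diagonal \code{NA}), \code{n_loci} (shared genotyped loci per
#'   pair), \code{ids}, and when \code{keep_parts} the per-locus parts
#'   (\code{num_parts}, \code{den_parts}, pair indices \code{pair_i},
#'   \code{pair_j}, \code{loci}).
#' @name kinship-estimators
NULL

# shared setup: allele fractions, masks, frequencies
.kin_setup <- function(g, freq_individuals) {
  g <- as_genotype_matrix(g)
  if (nrow(g) < 2) stop("at least two individuals required")
  x <- unclass(g)
  m <- !is.na(x)
  fi <- if (is.null(freq_individuals)) seq_len(nrow(x)) else freq_individuals
  if (is.character(fi)) fi <- match(fi, rownames(x))
  xf <- x[fi, , drop = FALSE]
  n_l <- colSums(!is.na(xf))
  p <- colSums(xf, na.rm = TRUE) / (2 * n_l)   # alt-allele frequency
  poly <- is.finite(p) & p > 0 & p < 1 & n_l >= 2
  if (!any(poly)) stop("no polymorphic locus with data; estimator undefined")
  list(x = x[, poly, drop = FALSE], m = m[, poly, drop = FALSE],
       p = p[poly], n_l = n_l[poly], ids = rownames(x),
       loci = colnames(x)[poly])
}

.pair_index <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = ut[, 1], j = ut[, 2])
}

.as_kinship <- function(estimator, num, den, m, setup, keep_parts, parts_fun) {
  vals <- num / den
  diag(vals) <- NA_real_
  n_loci <- tcrossprod(m * 1)
  diag(n_loci) <- NA_real_
  dimnames(vals) <- dimnames(n_loci) <- list(setup$ids, setup$ids)
  out <- list(estimator = estimator, values = vals, n_loci = n_loci,
              ids = setup$ids, loci = setup$loci)
  if (keep_parts) out <- c(out, parts_fun())
  structure(out, class = "kinship_matrix")
}

#' @rdname kinship-estimators
#' @export
loiselle_kinship <- function(g, freq_individuals = NULL, keep_parts = TRUE) {
  s <- .kin_setup(g, freq_individuals)
  a <- s$x / 2
  z <- a - rep(s$p, each = nrow(a))
  z[!s$m] <- 0
  cc <- s$p * (1 - s$p) / (s$n_l - 1)        # finite-sample correction
  w <- s$p * (1 - s$p)
  mm <- s$m * 1
  num <- tcrossprod(z) + tcrossprod(sweep(mm, 2, cc, "*"), mm)
  den <- tcrossprod(sweep(mm, 2, w, "*"), mm)
  .as_kinship("loiselle", num, den, s$m, s, keep_parts, function() {
    pi <- .pair_index(nrow(a))
    sh <- mm[pi$i, , drop = FALSE] * mm[pi$j, , drop = FALSE]
    list(num_parts = z[pi$i, , drop = FALSE] * z[pi$j, , drop = FALSE] +
           sweep(sh, 2, cc, "*"),
         den_parts = sweep(sh, 2, w, "*"),
         pair_i = pi$i, pair_j = pi$j)
  })
}

#' @rdname kinship-estimators
#' @export
ritland_kinship <- function(g, freq_individuals = NULL, keep_parts = TRUE) {
  s <- .kin_setup(g, freq_individuals)
  a <- s$x / 2
  b1 <- a; b1[!s$m] <- 0
  b2 <- (1 - a); b2[!s$m] <- 0
  b1 <- sweep(b1, 2, sqrt(s$p), "/")
  b2 <- sweep(b2, 2, sqrt(1 - s$p), "/")
  mm <- s$m * 1
  shared <- tcrossprod(mm)
  num <- tcrossprod(b1) + tcrossprod(b2) - shared
  .as_kinship("ritland", num, shared, s$m, s, keep_parts, function() {
    pi <- .pair_index(nrow(a))
    sh <- mm[pi$i, , drop = FALSE] * mm[pi$j, , drop = FALSE]
    np <- b1[pi$i, , drop = FALSE] * b1[pi$j, , drop = FALSE] +
      b2[pi$i, , drop = FALSE] * b2[pi$j, , drop = FALSE] - sh
    list(num_parts = np, den_parts = sh, pair_i = pi$i, pair_j = pi$j)
  })
}

#' @rdname kinship-estimators
#' @export
queller_goodnight <- function(g, freq_individuals = NULL, keep_parts = TRUE) {
  s <- .kin_setup(g, freq_individuals)
  gdos <- s$x
  mm <- s$m * 1
  g0 <- gdos; g0[!s$m] <- 0
  h0 <- (2 - gdos); h0[!s$m] <- 0
  # match count between the two alleles of x and the two of y, summed by pair
  s1 <- tcrossprod(g0) + tcrossprod(h0)
  # e_xl = expected matches of x's alleles with a random allele, masked
  e <- sweep(g0, 2, s$p, "*") + sweep(h0, 2, 1 - s$p, "*")
  exy <- tcrossprod(e, mm)                    # sum e_x over loci shared with y
  o <- (g0 == 0 | g0 == 2) * mm               # homozygote indicator, masked
  oxy <- tcrossprod(o, mm)
  shared <- tcrossprod(mm)
  num <- s1 - exy - t(exy)
  den <- 2 * shared + oxy + t(oxy) - exy - t(exy)
  den[abs(den) < 1e-12] <- NA_real_           # undefined pairs flagged
  .as_kinship("queller_goodnight", num, den, s$m, s, keep_parts, function() {
    pi <- .pair_index(nrow(gdos))
    sh <- mm[pi$i, , drop = FALSE] * mm[pi$j, , drop = FALSE]
    # e rows are masked by own genotype; multiplying by sh masks by partner
    np <- (g0[pi$i, , drop = FALSE] * g0[pi$j, , drop = FALSE] +
             h0[pi$i, , drop = FALSE] * h0[pi$j, , drop = FALSE]) -
      (e[pi$i, , drop = FALSE] + e[pi$j, , drop = FALSE]) * sh
    dp <- (2 + o[pi$i, , drop = FALSE] + o[pi$j, , drop = FALSE] -
             e[pi$i, , drop = FALSE] - e[pi$j, , drop = FALSE]) * sh
    list(num_parts = np, den_parts = dp, pair_i = pi$i, pair_j = pi$j)
  })
}

#' @export
print.kinship_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat(sprintf("kinship_matrix (%s): %d individuals, %d loci\n",
              x$estimator, length(x$ids), length(x$loci)))
  cat(sprintf("  mean pairwise value: %.4f (range %.4f to %.4f, %d undefined)\n",
              mean(v, na.rm = TRUE), min(v, na.rm = TRUE),
              max(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Convert between relationship and kinship coefficients
#'
#' Uses the identity R_ij = 2 F_ij / (1 + F_I), where F_I is the inbreeding
#' coefficient of the reference generation, to convert relationship
#' coefficients (e.g. Queller-Goodnight) to the kinship scale and back.
#'
#' @param r_value relationship coefficient(s).
#' @param f_value kinship coefficient(s).
#' @param f_i inbreeding coefficient; must exceed -1.
#' @return The converted coefficient(s).
#' @export
r_to_f <- function(r_value, f_i = 0) {
  if (any(f_i <= -1)) stop("f_i must exceed -1")
  r_value * (1 + f_i) / 2
}

#' @rdname r_to_f
#' @export
f_to_r <- function(f_value, f_i = 0) {
  if (any(f_i <= -1)) stop("f_i must exceed -1")
  2 * f_value / (1 + f_i)
}

#' Individual inbreeding coefficients
#'
#' Multilocus heterozygosity-deficit moment estimator:
#' \eqn{\hat F_i = 1 - \sum_l h_{il} / \sum_l 2 p_l (1 - p_l)}, a ratio of
#' sums over the individual's non-missing polymorphic loci (h = 1 when
#' heterozygous). The population mean carries a jackknife-across-loci 95%
#' confidence interval.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param freq_individuals optional frequency-group index as in the kinship
#'   estimators.
#' @return List of class \code{"inbreeding_estimates"}: \code{per_individual}
#'   (data frame id, f), \code{mean_f}, \code{se}, \code{ci95}, \code{n_loci}.
#' @export
inbreeding <- function(g, freq_individuals = NULL) {
  s <- .kin_setup(g, freq_individuals)
  h <- (s$x == 1) * 1
  h[!s$m] <- 0
  w <- 2 * s$p * (1 - s$p)
  mm <- s$m * 1
  num <- rowSums(h)
  den <- as.vector(mm %*% w)
  f <- 1 - num / den
  f[den == 0] <- NA_real_
  l <- ncol(mm)
  if (l >= 2) {
    # delete-one-locus pseudo-values of the population mean
    fm <- 1 - (num - h) / (den - sweep(mm, 2, w, "*"))
    mean_l <- colMeans(fm[den > 0, , drop = FALSE], na.rm = TRUE)
    se <- sqrt((l - 1) / l * sum((mean_l - mean(mean_l))^2))
  } else {
    se <- NA_real_
  }
  mean_f <- mean(f, na.rm = TRUE)
  structure(list(per_individual = data.frame(id = s$ids, f = f),
                 mean_f = mean_f, se = se,
                 ci95 = mean_f + c(-1.96, 1.96) * se,
                 n_loci = l),
            class = "inbreeding_estimates")
}

#' @export
print.inbreeding_estimates <- function(x, ...) {
  cat(sprintf("inbreeding: mean F = %.4f (95%% CI %.4f to %.4f, %d loci)\n",
              x$mean_f, x$ci95[1], x$ci95[2], x$n_loci))
  invisible(x)
}

#' Jackknife-across-loci uncertainty for a ratio-of-sums statistic
#'
#' Delete-one-locus jackknife for any statistic of the form
#' sum(numerators)/sum(denominators) over loci, the combining rule used by
#' every multilocus estimator in this package. The 95% CI uses the normal
#' multiplier 1.96.
#'
#' @param num_parts,den_parts per-locus numerator and denominator
#'   contributions (vectors of equal length, at least 2 loci).
#' @return List with \code{estimate}, \code{se}, \code{ci95} and the
#'   leave-one-out values \code{loo}.
#' @export
jackknife_ratio_ci <- function(num_parts, den_parts) {
  stopifnot(length(num_parts) == length(den_parts))
  l <- length(num_parts)
  if (l < 2) stop("jackknife requires at least 2 loci")
  est <- sum(num_parts) / sum(den_parts)
  loo <- (sum(num_parts) - num_parts) / (sum(den_parts) - den_parts)
  se <- sqrt((l - 1) / l * sum((loo - mean(loo))^2))
  list(estimate = est, se = se, ci95 = est + c(-1.96, 1.96) * se, loo = loo)
}
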