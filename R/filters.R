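#' Per-locus summary statistics
#'
#' Missing-data fraction, minor allele frequency (over non-missing genotypes
#' only), genotype counts, observed/expected heterozygosity and the exact
#' Hardy-Weinberg p-value for every locus.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param hwe compute the exact Hardy-Weinberg p-value per locus (default
#'   \code{TRUE}; set \code{FALSE} to skip on very large matrices).
#' @return A data frame with one row per locus: \code{locus}, \code{n_obs},
#'   \code{n_hom_ref}, \code{n_het}, \code{n_hom_alt}, \code{missing_fraction},
#'   \code{alt_freq}, \code{maf}, \code{het_obs}, \code{het_exp}, \code{hwe_p}.
#'   Loci with all genotypes missing get \code{NA} frequencies and are flagged
#'   in the \code{all_missing} column.
#' @export
locus_stats <- function(g, hwe = TRUE) {
  g <- as_genotype_matrix(g)
  if (nrow(g) < 1) stop("at least one individual required")
  x <- unclass(g)
  n_ind <- nrow(x)
  n_obs <- colSums(!is.na(x))
  n_het <- colSums(x == 1, na.rm = TRUE)
  n_hom_alt <- colSums(x == 2, na.rm = TRUE)
  n_hom_ref <- n_obs - n_het - n_hom_alt
  alt_freq <- ifelse(n_obs > 0, (n_het + 2 * n_hom_alt) / (2 * n_obs), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  het_obs <- ifelse(n_obs > 0, n_het / n_obs, NA_real_)
  het_exp <- 2 * alt_freq * (1 - alt_freq)
  hwe_p <- rep(NA_real_, ncol(x))
  if (hwe && any(n_obs > 0)) {
    has <- n_obs > 0
    hwe_p[has] <- mapply(hwe_exact_test, n_hom_ref[has], n_het[has],
                         n_hom_alt[has])
  }
  data.frame(locus = colnames(x), n_obs = n_obs, n_hom_ref = n_hom_ref,
             n_het = n_het, n_hom_alt = n_hom_alt,
             missing_fraction = 1 - n_obs / n_ind,
             alt_freq = alt_freq, maf = maf,
             het_obs = het_obs, het_exp = het_exp, hwe_p = hwe_p,
             all_missing = n_obs == 0, row.names = NULL)
}

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Exact conditional test: given the observed allele counts, the probability
#' of each possible heterozygote count follows the Levene distribution and the
#' p-value is the total probability of outcomes no more likely than the one
#' observed. Monomorphic loci return 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return Exact two-sided p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotyped individual required")
  n_a <- 2 * n_hom_ref + n_het   # reference allele count
  n_b <- 2 * n_hom_alt + n_het
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)  # feasible heterozygote counts
  # log P(n_het = h | allele counts): n! nA! nB! 2^h / ((2n)! nAA! h! nBB!)
  n_aa <- (n_a - hets) / 2
  n_bb <- (n_b - hets) / 2
  logp <- lgamma(n + 1) + lgamma(n_a + 1) + lgamma(n_b + 1) -
    lgamma(2 * n + 1) - lgamma(n_aa + 1) - lgamma(hets + 1) -
    lgamma(n_bb + 1) + hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Composite genotypic linkage-disequilibrium test
#'
#' Squared Pearson correlation of dosages over individuals genotyped at both
#' loci, with the chi-square approximation p = P(chisq_1 >= n r^2). Pairs with
#' fewer than three complete observations, or a constant dosage column, are
#' undefined and flagged (the pair is retained, not excluded).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param locus_a,locus_b locus names or column indices.
#' @return List with \code{r_squared}, \code{p}, \code{n} (complete pairs) and
#'   \code{defined}.
#' @export
ld_test <- function(g, locus_a, locus_b) {
  g <- as_genotype_matrix(g)
  a <- unclass(g)[, locus_a]
  b <- unclass(g)[, locus_b]
  keep <- !is.na(a) & !is.na(b)
  n <- sum(keep)
  if (n < 3 || stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0) {
    return(list(r_squared = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  r2 <- stats::cor(a[keep], b[keep])^2
  list(r_squared = r2,
       p = stats::pchisq(n * r2, df = 1, lower.tail = FALSE),
       n = n, defined = TRUE)
}

#' Sequential Bonferroni (Holm) rejections
#'
#' Step-down Holm procedure at family-wise level \code{alpha}, the standard
#' reading of the "sequential Bonferroni" correction. Thin wrapper around
#' \code{stats::p.adjust(method = "holm")}.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param alpha family-wise error level.
#' @return Logical vector of rejections (empty input gives an empty vector).
#' @export
holm_reject <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "holm") <= alpha
}

#' Filter specification for a missing-data / MAF cell
#'
#' @param max_missing per-locus missing-data ceiling in [0, 1] (inclusive).
#' @param min_maf minor-allele-frequency floor in [0, 0.5] (inclusive: loci at
#'   exactly the threshold are kept).
#' @param hwe_alpha family-wise level of the Holm-corrected exact
#'   Hardy-Weinberg screen; \code{NA} disables the screen.
#' @param ld_alpha family-wise level of the Holm-corrected pairwise LD screen;
#'   \code{NA} disables the screen.
#' @param one_snp_per_locus keep only the first SNP (lowest position) of each
#'   RAD-locus group.
#' @return An object of class \code{"filter_spec"}.
#' @export
filter_spec <- function(max_missing = 0.2, min_maf = 0.05, hwe_alpha = 0.05,
                        ld_alpha = 0.05, one_snp_per_locus = TRUE) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 0.5)
  structure(list(max_missing = max_missing, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, ld_alpha = ld_alpha,
                 one_snp_per_locus = one_snp_per_locus),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("filter_spec: MD <= %.2f, MAF >= %.2f, HWE alpha = %s, LD alpha = %s, one SNP/locus = %s\n",
              x$max_missing, x$min_maf, format(x$hwe_alpha),
              format(x$ld_alpha), x$one_snp_per_locus))
  invisible(x)
}

#' Apply a missing-data / MAF / HWE / LD filter to a genotype matrix
#'
#' Steps, in order: (1) drop loci with missing fraction above
#' \code{max_missing}; (2) drop loci with MAF below \code{min_maf}; (3) keep
#' one SNP (lowest position) per RAD-locus group; (4) drop loci failing the
#' exact Hardy-Weinberg test after Holm correction at \code{hwe_alpha};
#' (5) for each locus pair flagged by the Holm-corrected LD screen, drop the
#' later member. Each step's removal count is recorded in the attached log.
#' The operation is idempotent.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param spec a \code{\link{filter_spec}}.
#' @return The filtered \code{genotype_matrix} with attribute
#'   \code{filter_log} (data frame of step, n_before, n_removed) and
#'   \code{filter_spec}. An empty result triggers a warning, not an error.
#' @export
apply_filters <- function(g, spec = filter_spec()) {
  g <- as_genotype_matrix(g)
  stopifnot(inherits(spec, "filter_spec"))
  log <- list()
  note <- function(step, before, removed) {
    log[[length(log) + 1L]] <<- data.frame(step = step, n_before = before,
                                           n_removed = removed)
  }

  st <- locus_stats(g, hwe = FALSE)
  keep <- st$missing_fraction <= spec$max_missing & !st$all_missing
  note("missing_data", ncol(g), sum(!keep))
  g <- subset_genotypes(g, loci = keep)
  st <- st[keep, , drop = FALSE]

  keep <- !is.na(st$maf) & st$maf >= spec$min_maf
  note("maf", ncol(g), sum(!keep))
  g <- subset_genotypes(g, loci = keep)

  if (spec$one_snp_per_locus && !is.null(attr(g, "rad_locus")) && ncol(g) > 0) {
    rad <- attr(g, "rad_locus")
    pos <- attr(g, "position")
    if (is.null(pos)) pos <- seq_len(ncol(g))
    ord <- order(rad, pos)
    first <- ord[!duplicated(rad[ord])]
    keep <- sort(first)
    note("one_snp_per_locus", ncol(g), ncol(g) - length(keep))
    g <- subset_genotypes(g, loci = keep)
  }

  if (!is.na(spec$hwe_alpha) && ncol(g) > 0) {
    st <- locus_stats(g, hwe = TRUE)
    rej <- holm_reject(st$hwe_p, spec$hwe_alpha)
    rej[is.na(rej)] <- FALSE
    note("hwe", ncol(g), sum(rej))
    g <- subset_genotypes(g, loci = !rej)
  }

  if (!is.na(spec$ld_alpha) && ncol(g) > 1) {
    drop <- ld_screen(g, spec$ld_alpha)
    note("ld", ncol(g), length(drop))
    if (length(drop)) g <- subset_genotypes(g, loci = -drop)
  }

  if (ncol(g) == 0) warning("all loci removed by filtering")
  attr(g, "filter_log") <- do.call(rbind, log)
  attr(g, "filter_spec") <- spec
  g
}

# Holm-corrected pairwise LD screen; returns column indices to drop
# (the later member of each flagged pair still present).
ld_screen <- function(g, alpha) {
  x <- unclass(g)
  n_complete <- crossprod(!is.na(x))
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  r2 <- r^2
  ut <- upper.tri(r2)
  defined <- ut & is.finite(r2) & n_complete >= 3
  p <- stats::pchisq(n_complete[defined] * r2[defined], df = 1,
                     lower.tail = FALSE)
  if (!length(p)) return(integer(0))
  rej <- holm_reject(p, alpha)
  if (!any(rej)) return(integer(0))
  idx <- which(defined, arr.ind = TRUE)[rej, , drop = FALSE]
  dropped <- logical(ncol(x))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!dropped[i] && !dropped[j]) dropped[max(i, j)] <- TRUE
  }
  which(dropped)
}

#' Build the grid of filtered data sets over MD and MAF settings
#'
#' One filtered data set per (max missing, min MAF) cell, in Cartesian order
#' (MD varying slowest). With the study grid of five MD settings (0--20%) and
#' seven MAF settings (0.05--0.35) this yields 35 data sets.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param md_values vector of missing-data ceilings.
#' @param maf_values vector of MAF floors.
#' @param hwe_alpha,ld_alpha,one_snp_per_locus passed to
#'   \code{\link{filter_spec}}.
#' @return A list of class \code{"filter_grid"}; each element has \code{spec},
#'   \code{genotypes} and \code{n_snps}.
#' @export
make_grid_datasets <- function(g, md_values = c(0, 0.05, 0.10, 0.15, 0.20),
                               maf_values = seq(0.05, 0.35, by = 0.05),
                               hwe_alpha = NA, ld_alpha = NA,
                               one_snp_per_locus = TRUE) {
  if (!length(md_values) || !length(maf_values))
    stop("md_values and maf_values must be non-empty")
  g <- as_genotype_matrix(g)
  cells <- vector("list", length(md_values) * length(maf_values))
  k <- 0L
  for (md in md_values) {
    for (maf in maf_values) {
      k <- k + 1L
      spec <- filter_spec(max_missing = md, min_maf = maf,
                          hwe_alpha = hwe_alpha, ld_alpha = ld_alpha,
                          one_snp_per_locus = one_snp_per_locus)
      gf <- suppressWarnings(apply_filters(g, spec))
      cells[[k]] <- list(spec = spec, genotypes = gf, n_snps = ncol(gf))
    }
  }
  structure(cells, class = "filter_grid",
            md_values = md_values, maf_values = maf_values)
}

#' @export
print.filter_grid <- function(x, ...) {
  cat(sprintf("filter_grid: %d data sets (%d MD x %d MAF settings)\n",
              length(x), length(attr(x, "md_values")),
              length(attr(x, "maf_values"))))
  counts <- vapply(x, `[[`, numeric(1), "n_snps")
  cat("  SNP counts: ", paste(range(counts), collapse = " - "), "\n")
  invisible(x)
}
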