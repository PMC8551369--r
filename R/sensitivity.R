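#' Coefficient of variation (percent)
#'
#' 100 x sample standard deviation (n-1 denominator) over the absolute mean.
#'
#' @param values numeric vector (>= 2 values, non-zero mean).
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("CV requires at least two values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / abs(m)
}

#' Run SGS (and optionally parentage exclusion) over an MD x MAF grid
#'
#' For every (missing-data ceiling, MAF floor) cell the genotypes are
#' filtered and the requested analyses run with a per-cell seed derived
#' deterministically from the master seed and the cell position, so adding
#' cells never perturbs others. The SGS analysis records F1, slope, R^2 and
#' Sp for each of the three relatedness estimators; the parentage analysis
#' records the combined non-exclusion probability and cryptic gene flow.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param samples sample map data frame.
#' @param md_values,maf_values grid settings.
#' @param analyses subset of \code{c("sgs", "parentage")}.
#' @param n_classes distance classes for the SGS regression.
#' @param n_perm permutations per cell (0 disables the slope test; the grid
#'   summaries do not need it).
#' @param hwe_alpha,ld_alpha,one_snp_per_locus filter options (see
#'   \code{\link{filter_spec}}).
#' @param seed master seed.
#' @return Object of class \code{"sensitivity_report"}: a data frame with one
#'   row per cell plus summary methods.
#' @export
run_grid <- function(g, samples, md_values = c(0, 0.05, 0.10, 0.15, 0.20),
                     maf_values = seq(0.05, 0.35, by = 0.05),
                     analyses = c("sgs"), n_classes = 6, n_perm = 0,
                     hwe_alpha = NA, ld_alpha = NA, one_snp_per_locus = TRUE,
                     seed = NULL) {
  if (!length(md_values) || !length(maf_values)) stop("empty grid")
  g <- as_genotype_matrix(g)
  if (is.null(seed)) seed <- 0L
  estimators <- c("loiselle", "ritland", "queller_goodnight")
  rows <- list()
  for (i in seq_along(md_values)) {
    for (j in seq_along(maf_values)) {
      cell_seed <- (seed + 1009L * i + 31L * j) %% .Machine$integer.max
      spec <- filter_spec(max_missing = md_values[i], min_maf = maf_values[j],
                          hwe_alpha = hwe_alpha, ld_alpha = ld_alpha,
                          one_snp_per_locus = one_snp_per_locus)
      gf <- suppressWarnings(apply_filters(g, spec))
      row <- data.frame(md = md_values[i], maf = maf_values[j],
                        n_snps = ncol(gf))
      if (ncol(gf) == 0) {
        warning(sprintf("grid cell MD=%.2f MAF=%.2f retains no SNPs",
                        md_values[i], maf_values[j]))
        rows[[length(rows) + 1L]] <- row
        next
      }
      if ("sgs" %in% analyses) {
        for (est in estimators) {
          fit <- try(sgs(gf, samples, estimator = est, n_classes = n_classes,
                         n_perm = n_perm, jackknife = FALSE,
                         seed = cell_seed), silent = TRUE)
          vals <- if (inherits(fit, "try-error"))
            c(NA_real_, NA_real_, NA_real_, NA_real_)
          else c(fit$f1, fit$b, fit$r_squared, fit$sp)
          names(vals) <- paste0(c("f1_", "b_", "r2_", "sp_"), est)
          row <- cbind(row, as.data.frame(as.list(vals)))
        }
      }
      if ("parentage" %in% analyses) {
        cands <- samples$id[samples$reproductive == 1]
        ne <- non_exclusion_pp(allele_frequencies(gf, cands))
        row$log10_p_p <- ne$log10_p_p
        row$c_gf <- cryptic_gene_flow(ne$p_p, length(cands))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    # pad rows from empty cells so rbind aligns
    all_cols <- unique(unlist(lapply(rows, names)))
    r[setdiff(all_cols, names(r))] <- NA_real_
    r[all_cols]
  }))
  structure(out, class = c("sensitivity_report", "data.frame"),
            seed = seed, analyses = analyses)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity_report: %d grid cells, SNP counts %s\n",
              nrow(x), paste(range(x$n_snps), collapse = " - ")))
  print.data.frame(utils::head(as.data.frame(x)), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' @export
summary.sensitivity_report <- function(object, ...) {
  num <- setdiff(names(object)[vapply(object, is.numeric, TRUE)],
                 c("md", "maf"))
  tab <- data.frame(
    statistic = num,
    mean = vapply(num, function(c) mean(object[[c]], na.rm = TRUE), 0),
    sd = vapply(num, function(c) stats::sd(object[[c]], na.rm = TRUE), 0))
  tab$cv_percent <- 100 * tab$sd / abs(tab$mean)
  rownames(tab) <- NULL
  tab
}

#' Select the relatedness estimator with the most stable first-class kinship
#'
#' Picks the estimator whose F1 coefficient of variation across grid cells is
#' minimal; exact ties break toward the Loiselle estimator (then
#' alphabetically) and are reported via the \code{tie} attribute.
#'
#' @param report a \code{\link{run_grid}} report, or any data frame with
#'   \code{f1_<estimator>} columns.
#' @return The selected estimator name, with attribute \code{cv} giving the
#'   per-estimator CVs.
#' @export
select_estimator <- function(report) {
  cols <- grep("^f1_", names(report), value = TRUE)
  if (length(cols) < 2) {
    if (length(cols) == 1) return(sub("^f1_", "", cols))
    stop("report has no f1_<estimator> columns")
  }
  cvs <- vapply(cols, function(cc) cv_percent(report[[cc]]), 0)
  names(cvs) <- sub("^f1_", "", cols)
  best <- min(cvs)
  winners <- names(cvs)[cvs == best]
  pick <- if ("loiselle" %in% winners) "loiselle" else sort(winners)[1]
  structure(pick, cv = cvs, tie = length(winners) > 1)
}

#' Correlate a grid statistic with the number of SNPs
#'
#' Pearson correlation across grid cells between the chosen statistic and the
#' per-cell SNP count, with the two-tailed t-test p-value.
#'
#' @param report a \code{\link{run_grid}} report.
#' @param statistic column name, e.g. \code{"f1_loiselle"} or
#'   \code{"sp_loiselle"}.
#' @return List with \code{r}, \code{p}, \code{n} and \code{defined}.
#' @export
correlate_with_nsnps <- function(report, statistic) {
  stopifnot(statistic %in% names(report))
  y <- report[[statistic]]
  x <- report$n_snps
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 grid cells")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok), defined = FALSE))
  ct <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), defined = TRUE)
}
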