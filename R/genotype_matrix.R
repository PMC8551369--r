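#' Genotype matrix for biallelic SNP loci
#'
#' Container for individual-by-locus genotypes of strictly biallelic SNPs,
#' dosage-coded as the count of the alternate allele (0, 1, 2) with \code{NA}
#' marking missing calls. Loci may carry an optional grouping key assigning
#' SNPs to the RAD locus (assembled tag) they were called from, which drives
#' one-SNP-per-locus reduction in \code{\link{apply_filters}}.
#'
#' @param dosage integer or numeric matrix, individuals in rows and loci in
#'   columns; entries must be 0, 1, 2 or \code{NA}. Row and column names are
#'   used as individual and locus identifiers (defaults are generated when
#'   absent).
#' @param rad_locus optional character vector, one entry per locus, naming the
#'   RAD locus each SNP belongs to. When \code{NULL} every SNP is treated as
#'   its own locus.
#' @param position optional numeric vector of within-group positions used to
#'   order SNPs inside a RAD locus (lowest kept first).
#' @return An object of class \code{"genotype_matrix"}: the validated dosage
#'   matrix with attributes \code{rad_locus} and \code{position}.
#' @export
genotype_matrix <- function(dosage, rad_locus = NULL, position = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("dosage entries must be 0, 1, 2 or NA; offending value(s): ",
         paste(utils::head(unique(dosage[!ok]), 3L), collapse = ", "))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind_%03d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("snp_%05d", seq_len(ncol(dosage)))
  }
  if (anyDuplicated(rownames(dosage)))
    stop("individual identifiers must be unique")
  if (anyDuplicated(colnames(dosage)))
    stop("locus identifiers must be unique")
  if (!is.null(rad_locus)) {
    stopifnot(length(rad_locus) == ncol(dosage))
    rad_locus <- as.character(rad_locus)
  }
  if (!is.null(position)) stopifnot(length(position) == ncol(dosage))
  structure(dosage, rad_locus = rad_locus, position = position,
            class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci\n", nrow(x), ncol(x)))
  miss <- mean(is.na(x))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  if (!is.null(attr(x, "rad_locus"))) {
    cat(sprintf("  RAD-locus groups: %d\n",
                length(unique(attr(x, "rad_locus")))))
  }
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x object to coerce or test.
#' @export
as_genotype_matrix <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x)
  genotype_matrix(x)
}

#' @rdname genotype_matrix
#' @export
is_genotype_matrix <- function(x) inherits(x, "genotype_matrix")

#' Subset a genotype matrix by loci and/or individuals
#'
#' Keeps the RAD-locus grouping attributes aligned with the retained columns.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param loci logical, integer or character index of loci to keep.
#' @param individuals index of individuals to keep.
#' @return A \code{genotype_matrix}.
#' @export
subset_genotypes <- function(g, loci = NULL, individuals = NULL) {
  g <- as_genotype_matrix(g)
  if (is.null(loci)) loci <- seq_len(ncol(g))
  if (is.character(loci)) loci <- match(loci, colnames(g))
  if (is.logical(loci)) loci <- which(loci)
  if (is.null(individuals)) individuals <- seq_len(nrow(g))
  if (is.character(individuals)) individuals <- match(individuals, rownames(g))
  rad <- attr(g, "rad_locus")
  pos <- attr(g, "position")
  genotype_matrix(unclass(g)[individuals, loci, drop = FALSE],
                  rad_locus = if (!is.null(rad)) rad[loci],
                  position = if (!is.null(pos)) pos[loci])
}
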