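#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses the GT field of a VCF (v4.x) into a dosage-coded
#' \code{\link{genotype_matrix}}. Sites with more than one alternate allele
#' (or a missing ALT) are skipped and counted; \code{"./."}, \code{".|."} and
#' \code{"."} calls become \code{NA}. The CHROM field is retained as the
#' RAD-locus grouping key and POS as the within-group position, matching the
#' layout of de novo RAD assemblies where each assembled tag is a "chromosome".
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return A \code{genotype_matrix} (individuals x loci) with attribute
#'   \code{n_skipped} giving the number of non-biallelic sites dropped.
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & alt != "." & !grepl(",", alt) &
    nchar(alt) == 1L & nchar(ref) == 1L
  n_skipped <- sum(!biallelic)
  if (!any(biallelic)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  # dosage = number of "1" alleles in the call; any missing allele -> NA
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0", "0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1", "1")] <- 2
  ids <- paste(fix[biallelic, "CHROM"], fix[biallelic, "POS"], sep = "_")
  dimnames(dos) <- list(ids, colnames(gt))
  g <- genotype_matrix(t(dos),
                       rad_locus = fix[biallelic, "CHROM"],
                       position = as.numeric(fix[biallelic, "POS"]))
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Read or write a genotype dosage table
#'
#' Plain TSV interchange format: one row per individual, one column per locus,
#' a header row of locus identifiers and the first column (\code{id}) holding
#' individual identifiers; missing genotypes are \code{NA}.
#'
#' @param path file path.
#' @return \code{read_dosage_tsv} returns a \code{\link{genotype_matrix}}.
#' @export
read_dosage_tsv <- function(path) {
  if (!file.exists(path)) stop("dosage table not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  if (names(tab)[1] != "id") stop("first column of a dosage table must be 'id'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  if (ncol(m) == 0) stop("dosage table contains no loci")
  genotype_matrix(m)
}

#' @rdname read_dosage_tsv
#' @param g a \code{genotype_matrix} to write.
#' @export
write_dosage_tsv <- function(g, path) {
  g <- as_genotype_matrix(g)
  tab <- data.frame(id = rownames(g), unclass(g), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample map
#'
#' The sample map is a TSV with columns \code{id}, \code{x}, \code{y} (planar
#' coordinates, metres), \code{stage} (\code{"adult"} or \code{"seedling"})
#' and \code{reproductive} (0/1 flag; only reproductive adults are candidate
#' parents).
#'
#' @param path file path.
#' @return A data frame with the validated columns.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(tab)
}

#' @rdname read_sample_table
#' @param tab a data frame to validate in place of reading a file.
#' @export
validate_sample_table <- function(tab) {
  need <- c("id", "x", "y", "stage", "reproductive")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("sample table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$id)) stop("sample ids must be unique")
  if (!all(tab$stage %in% c("adult", "seedling")))
    stop("stage must be 'adult' or 'seedling'")
  if (!all(tab$reproductive %in% c(0, 1)))
    stop("reproductive must be 0 or 1")
  bad <- !is.finite(tab$x) | !is.finite(tab$y)
  if (any(bad))
    stop("non-finite coordinates for individual(s): ",
         paste(tab$id[bad], collapse = ", "))
  tab$id <- as.character(tab$id)
  tab
}
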