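# shared builders for small in-code fixtures

# minimal VCF text: records = list of c(chrom, pos, ref, alt, gt calls ...)
write_tiny_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r[1], r[2], ".", r[3], r[4], ".", "PASS", ".", "GT",
            r[-(1:4)]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

# genotype matrix from a literal individuals x loci layout
gm <- function(..., nrow) {
  genotype_matrix(matrix(c(...), nrow = nrow, byrow = TRUE))
}

# independent HWE exact-test oracle: Wigginton-style recurrence over the
# conditional heterozygote-count distribution (a different route than the
# lgamma formula used by the implementation)
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - rare * (n_a + n_b - rare) / (n_a + n_b)))
  probs[mid] <- 1
  if (mid < length(hets)) {
    for (k in mid:(length(hets) - 1)) {
      h <- hets[k]
      naa <- (n_a - h) / 2; nbb <- (n_b - h) / 2
      probs[k + 1] <- probs[k] * 4 * naa * nbb / ((h + 2) * (h + 1))
    }
  }
  if (mid > 1) {
    for (k in mid:2) {
      h <- hets[k]
      naa <- (n_a - h) / 2; nbb <- (n_b - h) / 2
      probs[k - 1] <- probs[k] * h * (h - 1) / (4 * (naa + 1) * (nbb + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# random HWE genotype matrix
random_hw_matrix <- function(n, l, freq_range = c(0.1, 0.9), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- runif(l, freq_range[1], freq_range[2])
  genotype_matrix(matrix(rbinom(n * l, 2, rep(q, each = n)), n, l))
}

# sample map with random coordinates
random_samples <- function(ids, arena = c(100, 100), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(id = ids, x = runif(length(ids), 0, arena[1]),
             y = runif(length(ids), 0, arena[2]),
             stage = "adult", reproductive = 1)
}

# mean pairwise estimate over the designated pairs of a pedigree simulation
pair_means <- function(g, kin) {
  prs <- attr(g, "pairs")
  idx <- cbind(match(prs[, 1], kin$ids), match(prs[, 2], kin$ids))
  mean(kin$values[idx], na.rm = TRUE)
}

djf_file <- function(name) system.file("extdata", name, package = "kinflow")
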