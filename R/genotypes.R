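#' Genotype table for an inbred accession panel
#'
#' Container for a panel of inbred accessions genotyped at biallelic SNPs.
#' Dosages are haploid-coded: 0 (reference allele), 1 (alternate allele) or
#' \code{NA} (missing).  Positions are 1-based and strictly increasing within
#' each chromosome.
#'
#' @param dosage numeric matrix, accessions x SNPs, values in \{0, 1, NA\};
#'   rownames are accession ids, colnames SNP ids.
#' @param snps data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based bp), \code{ref}, \code{alt}, one row per column of
#'   \code{dosage}, in the same order.
#' @return An object of class \code{genotype_table}: a list with elements
#'   \code{dosage} and \code{snps}.
#' @export
genotype_table <- function(dosage, snps) {
  if (!is.matrix(dosage)) stopf("dosage must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stopf("dosage needs accession rownames and SNP colnames")
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snps))) stopf("snps table lacks columns: %s",
                                         paste(setdiff(need, names(snps)), collapse = ", "))
  if (nrow(snps) != ncol(dosage)) stopf("snps rows (%d) != dosage columns (%d)",
                                        nrow(snps), ncol(dosage))
  if (!identical(as.character(snps$snp_id), colnames(dosage)))
    stopf("snps$snp_id must match dosage colnames in order")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stopf("dosage values must be 0, 1 or NA (haploid inbred coding)")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0)) stopf("positions not strictly increasing on %s", ch)
  }
  structure(list(dosage = dosage, snps = snps), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d accessions x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$snps$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  invisible(x)
}

#' Minor allele frequency per SNP
#'
#' Computes the pooled (or per-group) minor allele frequency from haploid
#' dosages, ignoring missing calls.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param groups optional named character/factor of group labels, one per
#'   accession (names = accession ids).  When given, a matrix with one row
#'   per group is returned.
#' @return numeric vector (pooled) or matrix (per group) of MAF in [0, 0.5].
#' @export
snp_maf <- function(gt, groups = NULL) {
  freq1 <- function(m) {
    p <- colMeans(m, na.rm = TRUE)
    p[is.nan(p)] <- NA_real_
    pmin(p, 1 - p)
  }
  if (is.null(groups)) return(freq1(gt$dosage))
  groups <- groups[rownames(gt$dosage)]
  labs <- sort(unique(as.character(groups)))
  out <- t(vapply(labs, function(g) freq1(gt$dosage[groups == g, , drop = FALSE]),
                  numeric(ncol(gt$dosage))))
  rownames(out) <- labs
  out
}

#' Hudson-type Fst between two groups
#'
#' Ratio-of-averages Hudson estimator over SNPs:
#' per-SNP numerator \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#' and denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}, summed before dividing.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param groups named vector of two group labels, one per accession.
#' @return single Fst estimate.
#' @export
fst_hudson <- function(gt, groups) {
  groups <- as.character(groups[rownames(gt$dosage)])
  labs <- sort(unique(groups))
  if (length(labs) != 2L) stopf("fst_hudson needs exactly two groups")
  d1 <- gt$dosage[groups == labs[1], , drop = FALSE]
  d2 <- gt$dosage[groups == labs[2], , drop = FALSE]
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE); p2 <- colMeans(d2, na.rm = TRUE)
  ok <- n1 >= 2 & n2 >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num[ok]) / sum(den[ok])
}

# Subset a genotype_table by accessions and/or SNP index, keeping order.
subset_genotypes <- function(gt, accessions = NULL, snp_idx = NULL) {
  d <- gt$dosage; s <- gt$snps
  if (!is.null(accessions)) d <- d[accessions, , drop = FALSE]
  if (!is.null(snp_idx)) {
    d <- d[, snp_idx, drop = FALSE]
    s <- s[snp_idx, , drop = FALSE]
  }
  structure(list(dosage = d, snps = s), class = "genotype_table")
}
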