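#' Site-wise nucleotide diversity
#'
#' Pairwise-difference definition for a biallelic site with allele counts
#' \code{(n_ref, n_alt)}: \eqn{\pi = n_{ref} n_{alt} / \binom{n}{2}} with
#' \eqn{n = n_{ref} + n_{alt}}.  Vectorized; sites with fewer than two
#' called alleles give \code{NA}.
#'
#' @param n_ref,n_alt reference/alternate allele counts.
#' @return numeric vector of per-site pi in [0, 1].
#' @export
site_pi <- function(n_ref, n_alt) {
  n <- n_ref + n_alt
  out <- n_ref * n_alt / (n * (n - 1) / 2)
  out[n < 2] <- NA_real_
  out
}

#' Per-group site diversity with a MAF filter
#'
#' Extracts each group's SNPs, removes sites with within-group
#' MAF < \code{maf_min}, and computes site-wise pi from the called allele
#' counts (missing dosages are excluded site-wise).  When
#' \code{equalize = TRUE}, the larger groups are subsampled (seeded) to the
#' smallest group's size before any computation, so sample size does not
#' drive diversity differences.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param groups named vector accession -> group label.
#' @param maf_min within-group MAF threshold (sites below are excluded).
#' @param equalize subsample all groups to the smallest group size.
#' @param seed seed for the subsampling.
#' @return data.frame: snp_id, chrom, pos, group, n, pi.
#' @export
group_pi <- function(gt, groups, maf_min = 0.05, equalize = FALSE, seed = 1L) {
  groups <- groups[rownames(gt$dosage)]
  by <- split(names(groups), as.character(groups))
  if (any(lengths(by) < 2)) stopf("every group needs at least 2 accessions")
  if (equalize) {
    n_min <- min(lengths(by))
    by <- lapply(seq_along(by), function(i) {
      a <- by[[i]]
      if (length(a) > n_min)
        sort(with_seed(derive_seed(seed, i), sample(a, n_min)))
      else a
    })
    names(by) <- names(split(names(groups), as.character(groups)))
  }
  out <- lapply(names(by), function(g) {
    d <- gt$dosage[by[[g]], , drop = FALSE]
    n_alt <- colSums(d, na.rm = TRUE)
    n <- colSums(!is.na(d))
    p <- ifelse(n > 0, n_alt / n, NA)
    maf <- pmin(p, 1 - p)
    keep <- which(!is.na(maf) & maf >= maf_min & n >= 2)
    data.frame(snp_id = gt$snps$snp_id[keep], chrom = gt$snps$chrom[keep],
               pos = gt$snps$pos[keep], group = g, n = n[keep],
               pi = site_pi(n[keep] - n_alt[keep], n_alt[keep]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Mean site diversity in windows
#'
#' Averages per-site pi over SNPs falling in each window (1-based closed
#' intervals), per group; windows without sites give \code{NA}.
#'
#' @param sites a \code{\link{group_pi}} table.
#' @param windows data.frame with \code{chrom}, \code{start}, \code{end}
#'   (and any label columns, which are carried through).
#' @return data.frame: windows replicated per group with \code{group},
#'   \code{mean_pi}, \code{n_sites} appended.
#' @export
window_mean_pi <- function(sites, windows) {
  out <- lapply(unique(sites$group), function(g) {
    s <- sites[sites$group == g, , drop = FALSE]
    mp <- numeric(nrow(windows)); ns <- integer(nrow(windows))
    for (i in seq_len(nrow(windows))) {
      sel <- s$chrom == windows$chrom[i] &
        s$pos >= windows$start[i] & s$pos <= windows$end[i]
      ns[i] <- sum(sel)
      mp[i] <- if (ns[i]) mean(s$pi[sel]) else NA_real_
    }
    cbind(windows, data.frame(group = g, mean_pi = mp, n_sites = ns,
                              stringsAsFactors = FALSE))
  })
  do.call(rbind, out)
}

#' Expression diversity (coefficient of variation) per gene and group
#'
#' CV = sample standard deviation / mean of accession-level normalized
#' expression (pre-log scale).  Genes with non-positive mean give \code{NA}.
#'
#' @param expr_acc genes x accessions matrix of normalized counts.
#' @param groups named vector accession -> group label.
#' @return data.frame: gene_id, group, cv.
#' @export
expression_cv <- function(expr_acc, groups) {
  groups <- groups[colnames(expr_acc)]
  out <- lapply(sort(unique(as.character(groups))), function(g) {
    m <- expr_acc[, groups == g, drop = FALSE]
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    data.frame(gene_id = rownames(expr_acc), group = g,
               cv = ifelse(mu > 0, s / mu, NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Size-factor normalized counts at the accession level
#'
#' Divides counts by the median-of-ratios size factors and averages
#' replicates within accession (pre-log scale, as used for CV).
#'
#' @param counts genes x samples raw counts.
#' @param samples sample table.
#' @return genes x accessions matrix of normalized mean counts.
#' @export
normalized_accession_counts <- function(counts, samples) {
  v <- normalize_vst(counts)
  sf <- attr(v, "size_factors")
  norm <- sweep(counts, 2L, sf, `/`)
  acc <- factor(samples$accession_id[match(colnames(counts), samples$sample_id)])
  M <- stats::model.matrix(~ acc - 1)
  ni <- as.vector(table(acc))
  out <- norm %*% sweep(M, 2L, ni, `/`)
  colnames(out) <- levels(acc)
  out
}
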