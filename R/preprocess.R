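#' Filter genes by the expressed-sample rule
#'
#' A gene is kept iff the number of samples with count >= \code{min_count}
#' is at least \code{ceiling(min_frac * n_samples)} ("expressed in at least
#' 20\% of the samples" at the 10-read threshold by default).
#'
#' @param counts genes x samples integer matrix.
#' @param min_count expression threshold on the raw count (default 10).
#' @param min_frac required fraction of samples, in (0, 1].
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, min_count = 10, min_frac = 0.20) {
  if (min_frac <= 0 || min_frac > 1) stopf("min_frac must be in (0, 1]")
  if (!nrow(counts)) stopf("empty count matrix")
  need <- ceiling(min_frac * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  rownames(counts)[keep]
}

#' Size-factor normalization with a variance-reducing log transform
#'
#' Median-of-ratios size factors (reference = per-gene geometric mean over
#' genes with no zero count), then \code{log2(count / s_j + 1)}.  This is a
#' monotone, approximately variance-stabilizing transform of normalized
#' counts; see the methods vignette for how it relates to spline-based VSTs.
#'
#' @param counts genes x samples integer matrix (>= 2 samples).
#' @return genes x samples matrix with attributes \code{transform = "vst"}
#'   and \code{size_factors}.
#' @export
normalize_vst <- function(counts) {
  if (ncol(counts) < 2) stopf("need at least 2 samples")
  pos <- rowSums(counts == 0) == 0
  if (any(pos)) {
    ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
    sf <- apply(counts[pos, , drop = FALSE], 2L, function(cj) median(cj / ref))
  } else {
    message("no zero-free gene for the median-of-ratios reference; ",
            "falling back to total-count size factors")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  }
  if (any(sf <= 0)) stopf("non-positive size factor")
  out <- log2(sweep(counts, 2L, sf, `/`) + 1)
  attr(out, "transform") <- "vst"
  attr(out, "size_factors") <- sf
  out
}

#' Rank-based inverse normal transform
#'
#' Maps values to quantiles of the standard normal,
#' \eqn{\Phi^{-1}((r_i - 0.5)/n)}, with ties broken randomly under the seed.
#'
#' @param x numeric vector (length >= 2, finite).
#' @param seed optional integer governing tie-breaking only.
#' @return transformed vector.
#' @export
inverse_normal_transform <- function(x, seed = NULL) {
  n <- length(x)
  if (n < 2) stopf("need at least 2 values")
  if (any(!is.finite(x))) stopf("non-finite values")
  if (length(unique(x)) == 1L) warnf("all values identical; ranks are random")
  r <- with_seed(seed, rank(x, ties.method = "random"))
  qnorm((r - 0.5) / n)
}

#' Inverse normal transform of every row of a matrix
#'
#' @param mat genes x samples (or genes x accessions) matrix.
#' @param seed base seed; each row uses an independently derived stream for
#'   its tie-breaking.
#' @return matrix of the same shape, attribute \code{transform = "int"}.
#' @export
int_rows <- function(mat, seed = 1L) {
  out <- mat
  for (i in seq_len(nrow(mat)))
    out[i, ] <- inverse_normal_transform(mat[i, ], seed = derive_seed(seed, i))
  attr(out, "transform") <- "int"
  out
}

#' Principal component analysis of the genotype matrix
#'
#' Removes SNPs with pooled MAF below \code{maf_min}, imputes missing
#' dosages to the column mean, centers columns and takes the singular value
#' decomposition.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param maf_min SNPs with MAF < maf_min are removed (default 0.10).
#' @param k number of components to return.
#' @return object of class \code{pca_result}: list with \code{scores}
#'   (accessions x k) and \code{pve} (proportion of variance explained).
#' @export
genotype_pca <- function(gt, maf_min = 0.10, k = 4) {
  maf <- snp_maf(gt)
  keep <- which(!is.na(maf) & maf >= maf_min)
  if (length(keep) < k) stopf("fewer than k SNPs pass the MAF filter")
  x <- gt$dosage[, keep, drop = FALSE]
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  k <- min(k, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- rownames(gt$dosage)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, pve = (sv$d^2 / sum(sv$d^2))[seq_len(k)]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d accessions, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  PVE:", paste(sprintf("%.1f%%", 100 * x$pve), collapse = " "), "\n")
  invisible(x)
}

#' Classify accessions into the two subspecies from PC1
#'
#' Stand-in for model-based admixture classification: 2-means clustering on
#' the first genotype principal component, with clusters named by the
#' anchors' majority label.
#'
#' @param pca a \code{\link{genotype_pca}} result.
#' @param anchors named character vector (accession -> known label) with at
#'   least one accession per label; exactly two labels.
#' @return object of class \code{subspecies_assignment}: named character
#'   vector accession -> label, with a \code{method} attribute.
#' @export
classify_subspecies <- function(pca, anchors) {
  labs <- sort(unique(anchors))
  if (length(labs) != 2L) stopf("anchors must carry exactly two labels")
  pc1 <- pca$scores[, 1]
  ctr <- matrix(range(pc1), ncol = 1)
  km <- kmeans(matrix(pc1, ncol = 1), centers = ctr)
  cl <- setNames(km$cluster, names(pc1))
  if (any(tabulate(km$cluster, 2L) == 0L)) stopf("empty cluster")
  name_of <- character(2)
  for (g in 1:2) {
    a <- anchors[names(anchors) %in% names(cl)[cl == g]]
    if (!length(a)) next
    tab <- table(a)
    name_of[g] <- names(tab)[which.max(tab)]
  }
  if (any(name_of == "")) {
    # a cluster without anchors takes the remaining label
    name_of[name_of == ""] <- setdiff(labs, name_of)
  }
  if (name_of[1] == name_of[2])
    stopf("anchor conflict: both clusters map to label %s", name_of[1])
  out <- setNames(name_of[cl], names(cl))
  # anchors sitting in the "wrong" cluster would be silent errors downstream
  mis <- names(anchors)[anchors != out[names(anchors)]]
  if (length(mis) > length(anchors) / 2)
    stopf("anchor conflict: majority of anchors disagree with clustering")
  attr(out, "method") <- "pca_kmeans"
  class(out) <- "subspecies_assignment"
  out
}

#' @export
print.subspecies_assignment <- function(x, ...) {
  tab <- table(unclass(x))
  cat("subspecies_assignment:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("(method: %s)\n", attr(x, "method")))
  invisible(x)
}

#' Accession-level BLUPs of replicate expression
#'
#' Per gene, fits the one-way random-intercept model
#' \eqn{y_{ij} = \mu + u_i + e_{ij}} by REML and returns the shrinkage
#' predictor \eqn{\hat\mu + w_i (\bar y_i - \hat\mu)} with
#' \eqn{w_i = \hat\sigma^2_a / (\hat\sigma^2_a + \hat\sigma^2_e / r_i)}.
#'
#' @param expr genes x samples matrix of transformed expression.
#' @param samples sample table with \code{sample_id} and \code{accession_id}
#'   matching the columns of \code{expr}.
#' @return genes x accessions matrix of BLUPs, attribute
#'   \code{transform = "blup"}.
#' @export
accession_blup <- function(expr, samples) {
  acc <- factor(samples$accession_id[match(colnames(expr), samples$sample_id)])
  ni <- as.vector(table(acc))
  if (all(ni == 1L)) {
    warnf("single replicate everywhere; BLUPs equal observed values")
    out <- expr
    colnames(out) <- as.character(acc)
    attr(out, "transform") <- "blup"
    return(out)
  }
  st <- oneway_stats(expr, acc)
  out <- matrix(NA_real_, nrow(expr), nlevels(acc),
                dimnames = list(rownames(expr), levels(acc)))
  for (g in seq_len(nrow(expr))) {
    fit <- reml_oneway(st$means[g, ], st$ssw[g], st$ni)
    w <- fit$sigma_a2 / (fit$sigma_a2 + fit$sigma_e2 / st$ni)
    w[is.nan(w)] <- 0
    out[g, ] <- fit$mu + w * (st$means[g, ] - fit$mu)
  }
  attr(out, "transform") <- "blup"
  out
}
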