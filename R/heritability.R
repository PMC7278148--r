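#' Broad-sense heritability of expression
#'
#' Per gene, REML variance components of the one-way random-intercept model
#' (accession as random effect) on replicate-level transformed expression.
#' \eqn{H^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)}; the restricted
#' likelihood-ratio statistic tests \eqn{\sigma^2_a = 0}.  Balanced designs
#' use the closed-form ANOVA solution (negative estimates truncated at 0).
#'
#' @param expr genes x samples matrix of transformed expression.
#' @param samples sample table (\code{sample_id}, \code{accession_id}).
#' @return data.frame: gene_id, sigma_a2, sigma_e2, H2, rlrt.  The design
#'   (accession sizes) is attached as attribute \code{ni}.
#' @export
fit_broad_h2 <- function(expr, samples) {
  acc <- factor(samples$accession_id[match(colnames(expr), samples$sample_id)])
  ni <- as.vector(table(acc))
  if (all(ni == 1L)) stopf("single replicate per accession: variance components inseparable")
  st <- oneway_stats(expr, acc)
  a <- length(ni); N <- sum(ni)
  if (length(unique(ni)) == 1L) {
    r <- ni[1]
    gm <- rowMeans(st$means)
    ssb <- r * rowSums((st$means - gm)^2)
    msb <- ssb / (a - 1); msw <- st$ssw / (N - a)
    sigma_a2 <- pmax(0, (msb - msw) / r)
    sigma_e2 <- ifelse(sigma_a2 > 0, msw, (ssb + st$ssw) / (N - 1))
    H2 <- sigma_a2 / (sigma_a2 + sigma_e2)
    rlrt <- rlrt_balanced(ssb, st$ssw, a, N)
  } else {
    sigma_a2 <- sigma_e2 <- H2 <- rlrt <- numeric(nrow(expr))
    for (g in seq_len(nrow(expr))) {
      fit <- reml_oneway(st$means[g, ], st$ssw[g], ni)
      sigma_a2[g] <- fit$sigma_a2; sigma_e2[g] <- fit$sigma_e2
      H2[g] <- fit$H2; rlrt[g] <- fit$rlrt
    }
  }
  out <- data.frame(gene_id = rownames(expr), sigma_a2 = sigma_a2,
                    sigma_e2 = sigma_e2, H2 = H2, rlrt = rlrt,
                    stringsAsFactors = FALSE)
  attr(out, "ni") <- ni
  out
}

#' Simulated null distribution of the restricted LRT
#'
#' The null distribution of the one-way restricted LRT depends only on the
#' design (accession replicate counts), so one simulated distribution serves
#' every gene sharing the design.  Roughly half the null mass sits at 0
#' (boundary behavior).
#'
#' @param ni vector of replicates per accession.
#' @param B number of null draws (default 10000).
#' @param seed RNG seed.
#' @return sorted numeric vector of B null statistics.
#' @export
rlrt_null <- function(ni, B = 10000, seed = 1L) {
  a <- length(ni); N <- sum(ni)
  with_seed(seed, {
    if (length(unique(ni)) == 1L) {
      ssb <- rchisq(B, a - 1)
      ssw <- rchisq(B, N - a)
      null <- rlrt_balanced(ssb, ssw, a, N)
    } else {
      null <- numeric(B)
      for (b in seq_len(B)) {
        m <- rnorm(a, 0, sqrt(1 / ni))
        ssw <- rchisq(1, N - a)
        null[b] <- reml_oneway(m, ssw, ni)$rlrt
      }
    }
    sort(null)
  })
}

#' Empirical p-values against a simulated null
#'
#' Add-one convention: \eqn{p = (1 + \#\{null \ge obs\}) / (B + 1)}.
#'
#' @param obs observed statistics.
#' @param null sorted null draws (e.g. \code{\link{rlrt_null}}).
#' @return vector of empirical p-values.
#' @export
empirical_p <- function(obs, null) {
  B <- length(null)
  n_ge <- B - findInterval(obs - 1e-12, null)
  (1 + n_ge) / (B + 1)
}

#' Genomic relationship matrix (VanRaden)
#'
#' \eqn{G = Z_{cs} Z_{cs}' / m} with columns of the dosage matrix centered
#' and scaled to unit population variance (denominator n); monomorphic
#' columns are dropped and missing dosages imputed to the column mean.  The
#' scaling forces \code{mean(diag(G)) == 1}.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @return object of class \code{grm}: list with \code{G}, \code{accessions},
#'   \code{m} (markers used).
#' @export
build_grm <- function(gt) {
  x <- gt$dosage
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  n <- nrow(x)
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2          # population variance, denominator n
  keep <- v > 1e-12
  if (!any(keep)) stopf("all SNP columns are monomorphic")
  z <- sweep(x[, keep, drop = FALSE], 2L, mu[keep], `-`)
  z <- sweep(z, 2L, sqrt(v[keep]), `/`)
  m <- sum(keep)
  structure(list(G = tcrossprod(z) / m, accessions = rownames(x), m = m),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d accessions, %d markers; mean(diag) = %.6f\n",
              nrow(x$G), x$m, mean(diag(x$G))))
  invisible(x)
}

# Spectral REML machinery for y ~ N(Xb, sigma_g^2 G + sigma_e^2 I).
# One eigendecomposition of G serves all genes; each gene is a 1-D profile
# over log lambda (lambda = sigma_g^2 / sigma_e^2).
grm_eigen <- function(grm) {
  e <- eigen(grm$G, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e
}

m2ll_reml_grm <- function(lambda, yt, xt, d) {
  w <- lambda * d + 1
  xtwx <- sum(xt^2 / w)
  b <- sum(xt * yt / w) / xtwx
  Q <- max(sum((yt - xt * b)^2 / w), 1e-300)
  n <- length(yt)
  (n - 1) * log(Q / (n - 1)) + sum(log(w)) + log(xtwx) + (n - 1)
}

#' Narrow-sense heritability via GRM REML
#'
#' Per gene, profiles the restricted likelihood of
#' \eqn{y \sim N(\mu 1, \sigma^2_g G + \sigma^2_e I)} over
#' \eqn{\log\lambda \in [-10, 10]} (\eqn{\lambda = \sigma^2_g/\sigma^2_e})
#' after one spectral decomposition of G.  \eqn{h^2 = \lambda/(1+\lambda)}.
#' The restricted LRT against \eqn{\sigma^2_g = 0} is referred, by default,
#' to a simulated finite-sample null for the design (the null depends only
#' on the GRM spectrum, so one simulation serves all genes); the
#' \eqn{0.5\chi^2_0 + 0.5\chi^2_1} boundary mixture is available but runs
#' conservative at moderate sample sizes, where more than half the null
#' mass sits on the boundary.
#'
#' @param Y genes x accessions matrix of accession-level expression
#'   (columns aligned to \code{grm$accessions}).
#' @param grm a \code{\link{build_grm}} result.
#' @param null "simulated" (default), "mixture", or "none" (skip p-values).
#' @param B_null draws for the simulated null.
#' @param seed seed for the simulated null.
#' @return data.frame: gene_id, sigma_g2, sigma_e2, lambda, h2, lrt, p.
#' @export
fit_narrow_h2 <- function(Y, grm, null = c("simulated", "mixture", "none"),
                          B_null = 2000, seed = 1L) {
  null <- match.arg(null)
  if (!identical(colnames(Y), grm$accessions))
    Y <- Y[, grm$accessions, drop = FALSE]
  e <- grm_eigen(grm)
  d <- e$values
  Ut <- t(e$vectors)
  xt <- as.vector(Ut %*% rep(1, length(d)))
  n <- length(d)
  res <- matrix(NA_real_, nrow(Y), 6)
  for (g in seq_len(nrow(Y))) {
    yt <- as.vector(Ut %*% Y[g, ])
    if (!all(is.finite(yt))) next
    f <- function(ll) m2ll_reml_grm(exp(ll), yt, xt, d)
    opt <- optimize(f, c(-10, 10))
    v0 <- m2ll_reml_grm(0, yt, xt, d)
    if (v0 <= opt$objective + 1e-10) {
      lam <- 0; obj <- v0
    } else {
      lam <- exp(opt$minimum); obj <- opt$objective
    }
    w <- lam * d + 1
    xtwx <- sum(xt^2 / w)
    b <- sum(xt * yt / w) / xtwx
    Q <- sum((yt - xt * b)^2 / w)
    se2 <- Q / (n - 1)
    lrt <- max(0, v0 - obj)
    res[g, ] <- c(lam * se2, se2, lam, lam / (1 + lam), lrt, NA)
  }
  out <- data.frame(gene_id = rownames(Y), sigma_g2 = res[, 1],
                    sigma_e2 = res[, 2], lambda = res[, 3], h2 = res[, 4],
                    lrt = res[, 5], p = NA_real_, stringsAsFactors = FALSE)
  if (null == "mixture") {
    out$p <- ifelse(out$lrt <= 1e-10, 1,
                    0.5 * pchisq(out$lrt, df = 1, lower.tail = FALSE))
  } else if (null == "simulated") {
    nd <- narrow_lrt_null(d, xt, B = B_null, seed = seed)
    out$p <- empirical_p(out$lrt, nd)
  }
  out
}

# Simulated null distribution of the GRM restricted LRT: under
# sigma_g^2 = 0 the rotated response is iid normal, so the null depends
# only on the GRM spectrum and the rotated intercept.
narrow_lrt_null <- function(d, xt, B = 2000, seed = 1L) {
  with_seed(seed, {
    n <- length(d)
    out <- numeric(B)
    for (b in seq_len(B)) {
      yt <- rnorm(n)
      f <- function(ll) m2ll_reml_grm(exp(ll), yt, xt, d)
      opt <- optimize(f, c(-10, 10))
      out[b] <- max(0, m2ll_reml_grm(0, yt, xt, d) - opt$objective)
    }
    sort(out)
  })
}

#' Within-subspecies heritability
#'
#' Subsamples the larger subspecies to the smaller's size (seeded),
#' re-applies the expression filter within each subspecies, and fits broad-
#' and narrow-sense heritability per scope.  Broad-sense p-values come from
#' a simulated restricted-LRT null for the scope's design; narrow-sense
#' p-values from the chi-square boundary mixture.
#'
#' @param counts genes x samples raw counts.
#' @param samples sample table.
#' @param genotypes a \code{\link{genotype_table}}.
#' @param assignment subspecies assignment (accession -> I/J).
#' @param seed seed for the subsampling and transforms.
#' @param min_count,min_frac within-subspecies expression filter.
#' @param B_null draws for the broad-sense RLRT null.
#' @param fdr significance threshold on q (default 0.001).
#' @return list with one element per scope (\code{I}, \code{J}): each a list
#'   of \code{broad} and \code{narrow} data.frames (with p and q), plus
#'   \code{accessions} used per scope.
#' @export
within_subspecies_h2 <- function(counts, samples, genotypes, assignment,
                                 seed = 1L, min_count = 10, min_frac = 0.20,
                                 B_null = 10000, fdr = 0.001) {
  lab <- unclass(assignment)
  acc_by <- split(names(lab), lab)
  if (length(acc_by) != 2L) stopf("need exactly two subspecies")
  n_min <- min(lengths(acc_by))
  used <- lapply(names(acc_by), function(k) {
    a <- acc_by[[k]]
    if (length(a) > n_min) sort(with_seed(derive_seed(seed, match(k, names(acc_by))),
                                          sample(a, n_min))) else sort(a)
  })
  names(used) <- names(acc_by)
  out <- list()
  for (k in names(used)) {
    smp <- samples[samples$accession_id %in% used[[k]], , drop = FALSE]
    cnt <- counts[, smp$sample_id, drop = FALSE]
    keep <- filter_expressed(cnt, min_count = min_count, min_frac = min_frac)
    expr <- int_rows(normalize_vst(cnt[keep, , drop = FALSE]),
                     seed = derive_seed(seed, 10L + match(k, names(used))))
    broad <- fit_broad_h2(expr, smp)
    null <- rlrt_null(attr(broad, "ni"), B = B_null,
                      seed = derive_seed(seed, 20L + match(k, names(used))))
    broad$p <- empirical_p(broad$rlrt, null)
    broad$q <- bh_adjust(broad$p)
    broad$significant <- broad$q <= fdr
    gts <- subset_genotypes(genotypes, accessions = used[[k]])
    grm <- build_grm(gts)
    blup <- accession_blup(expr, smp)
    yacc <- int_rows(blup, seed = derive_seed(seed, 30L + match(k, names(used))))
    narrow <- fit_narrow_h2(yacc, grm, B_null = B_null,
                            seed = derive_seed(seed, 40L + match(k, names(used))))
    narrow$q <- bh_adjust(narrow$p)
    narrow$significant <- !is.na(narrow$q) & narrow$q <= fdr
    out[[k]] <- list(broad = broad, narrow = narrow, accessions = used[[k]])
  }
  out
}

#' Permutation test for between-group heritability differences
#'
#' Null distribution of \eqn{\Delta H^2} (or \eqn{\Delta h^2}): in each of B
#' rounds the accessions are randomly partitioned, ignoring subspecies
#' labels, into two disjoint groups of \code{group_size}; heritability is
#' estimated per group and the difference recorded.  The same B partitions
#' are evaluated for every gene (the resampling is of accessions, not of
#' expression).  Two-sided empirical p with the add-one convention.
#'
#' @param delta_obs named vector of observed differences (J minus I), one
#'   per gene.
#' @param kind "broad" (replicate-level data) or "narrow" (GRM REML on
#'   accession-level data).
#' @param expr genes x samples transformed expression (broad kind).
#' @param samples sample table (broad kind).
#' @param Y genes x accessions matrix (narrow kind).
#' @param genotypes \code{genotype_table} covering the accessions (narrow).
#' @param group_size accessions per permuted group (default: half the panel,
#'   capped at the smaller subspecies size by the caller).
#' @param B permutation rounds (default 100).
#' @param seed RNG seed for the partitions.
#' @return data.frame of class \code{delta_h_result}: gene_id, kind, delta,
#'   p, B.
#' @export
delta_h_permutation <- function(delta_obs, kind = c("broad", "narrow"),
                                expr = NULL, samples = NULL,
                                Y = NULL, genotypes = NULL,
                                group_size, B = 100, seed = 1L) {
  kind <- match.arg(kind)
  if (B < 1) stopf("B must be >= 1")
  genes <- names(delta_obs)
  if (kind == "broad") {
    stopifnot(!is.null(expr), !is.null(samples))
    expr <- expr[genes, , drop = FALSE]
    acc <- factor(samples$accession_id[match(colnames(expr), samples$sample_id)])
    ni <- as.vector(table(acc))
    if (length(unique(ni)) != 1L)
      stopf("broad-kind permutation requires a balanced design")
    r <- ni[1]
    st <- oneway_stats(expr, acc)
    # per-accession within-SS per gene
    M <- stats::model.matrix(~ acc - 1)
    ssw_acc <- (expr^2) %*% M - sweep(st$means^2, 2L, ni, `*`)
    colnames(ssw_acc) <- st$levels
    accs <- st$levels
    a <- group_size; n_within <- a * (r - 1); N <- a * r
    h2_of <- function(grp) {
      m <- st$means[, grp, drop = FALSE]
      ssb <- r * rowSums((m - rowMeans(m))^2)
      ssw <- rowSums(ssw_acc[, grp, drop = FALSE])
      msb <- ssb / (a - 1); msw <- ssw / (N - a)
      sa <- pmax(0, (msb - msw) / r)
      se <- ifelse(sa > 0, msw, (ssb + ssw) / (N - 1))
      sa / (sa + se)
    }
  } else {
    stopifnot(!is.null(Y), !is.null(genotypes))
    Y <- Y[genes, , drop = FALSE]
    accs <- colnames(Y)
    h2_of <- function(grp) {
      gts <- subset_genotypes(genotypes, accessions = grp)
      grm <- build_grm(gts)
      fit_narrow_h2(Y[, grp, drop = FALSE], grm, null = "none")$h2
    }
  }
  if (2 * group_size > length(accs))
    stopf("group_size too large for %d accessions", length(accs))
  exceed <- integer(length(genes))
  for (b in seq_len(B)) {
    pick <- with_seed(derive_seed(seed, 1000L + b),
                      sample(accs, 2 * group_size))
    g1 <- pick[seq_len(group_size)]
    g2 <- pick[group_size + seq_len(group_size)]
    dn <- h2_of(g2) - h2_of(g1)
    exceed <- exceed + (abs(dn) >= abs(delta_obs) - 1e-12)
  }
  out <- data.frame(gene_id = genes, kind = kind, delta = unname(delta_obs),
                    p = (1 + exceed) / (B + 1), B = B,
                    stringsAsFactors = FALSE)
  class(out) <- c("delta_h_result", "data.frame")
  out
}
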