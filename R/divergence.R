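#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; \code{NA}s are passed through and do not count
#' toward the number of tests.
#'
#' @param p vector of p-values in [0, 1] (NAs allowed).
#' @return vector of adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values outside [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

# Internal: accession-level subspecies covariate, symmetric +/- 0.5 coding
# (J = +0.5).  Symmetric coding keeps penalized logistic fits invariant to
# which subspecies is called the reference.
subspecies_code <- function(acc_levels, assignment) {
  s <- unclass(assignment)[acc_levels]
  if (anyNA(s)) stopf("assignment missing for accession(s): %s",
                      paste(acc_levels[is.na(s)], collapse = ", "))
  ifelse(s == "J", 0.5, -0.5)
}

#' Differential expression scan between subspecies
#'
#' Per gene, maximum-likelihood fits of the linear mixed model
#' \eqn{y = \mu + \beta S + u_{acc} + e} and the reduced model without the
#' subspecies term; the likelihood-ratio statistic is referred to
#' chi-square(1).  \eqn{\beta} is the Japonica-minus-Indica contrast on the
#' transformed scale.
#'
#' @param expr genes x samples matrix of (inverse-normal transformed)
#'   expression.
#' @param samples sample table (\code{sample_id}, \code{accession_id}).
#' @param assignment a \code{subspecies_assignment} (accession -> I/J).
#' @param fdr significance threshold on the BH-adjusted q (default 0.001).
#' @return data.frame of class \code{divergence_result}: gene_id, test,
#'   beta, mu, lrt, p, q, direction, significant.
#' @export
de_scan <- function(expr, samples, assignment, fdr = 0.001) {
  acc <- factor(samples$accession_id[match(colnames(expr), samples$sample_id)])
  st <- oneway_stats(expr, acc)
  S <- subspecies_code(st$levels, assignment)
  if (length(unique(S)) < 2) stopf("need accessions from both subspecies")
  Xf <- cbind(1, S); Xr <- cbind(rep(1, length(S)))
  n_genes <- nrow(expr)
  beta <- mu <- lrt <- p <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    full <- ml_oneway(st$means[g, ], st$ssw[g], st$ni, Xf)
    red <- ml_oneway(st$means[g, ], st$ssw[g], st$ni, Xr)
    lrt[g] <- max(0, red$m2ll - full$m2ll)
    p[g] <- pchisq(lrt[g], df = 1, lower.tail = FALSE)
    beta[g] <- full$beta[2]; mu[g] <- full$beta[1]
  }
  q <- bh_adjust(p)
  out <- data.frame(gene_id = rownames(expr), test = "DE", beta = beta,
                    mu = mu, lrt = lrt, p = p, q = q,
                    direction = ifelse(beta > 0, "higher-in-J", "higher-in-I"),
                    significant = !is.na(q) & q <= fdr,
                    stringsAsFactors = FALSE)
  class(out) <- c("divergence_result", "data.frame")
  out
}

#' Differential-expression test for a single gene
#'
#' @param y named vector of transformed expression (names = sample ids).
#' @inheritParams de_scan
#' @return one-row \code{divergence_result} data.frame.
#' @export
fit_de_gene <- function(y, samples, assignment) {
  m <- matrix(y, nrow = 1, dimnames = list("gene", names(y)))
  de_scan(m, samples, assignment)[1, ]
}

#' Binary presence/absence coding and the PAV candidate band
#'
#' Samples with count strictly greater than \code{threshold} are coded
#' expressed (1).  Candidate genes are those with expressed-sample fraction
#' inside \code{[lower, upper]}.
#'
#' @param counts genes x samples raw counts.
#' @param threshold read-count threshold (expressed iff count > threshold).
#' @param lower,upper candidate band on the expressed fraction.
#' @return list with \code{binary} (genes x samples 0/1 matrix) and
#'   \code{candidates} (gene ids in the band).
#' @export
encode_pav <- function(counts, threshold = 10, lower = 0.20, upper = 0.80) {
  bin <- (counts > threshold) * 1L
  frac <- rowMeans(bin)
  list(binary = bin,
       candidates = rownames(counts)[frac >= lower & frac <= upper])
}

# Penalized marginal log-likelihood of the random-intercept logistic model,
# integrated per accession by adaptive Gauss-Hermite quadrature.
# s: successes per accession, n: trials per accession, X: a x p design,
# theta = c(beta, log sigma_a).  Ridge: beta ~ N(0, ridge_var I).
pav_loglik <- function(theta, s, n, X, gh, ridge_var) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sig <- exp(theta[p + 1])
  eta0 <- as.vector(X %*% beta)
  # Newton to the per-accession posterior mode of the random intercept
  u <- rep(0, length(s))
  for (it in 1:40) {
    pr <- plogis(eta0 + u)
    g1 <- s - n * pr - u / sig^2
    g2 <- -(n * pr * (1 - pr) + 1 / sig^2)
    step <- g1 / g2
    u <- u - step
    if (max(abs(step)) < 1e-10) break
  }
  pr <- plogis(eta0 + u)
  tau <- 1 / sqrt(n * pr * (1 - pr) + 1 / sig^2)
  # integrand log g(u) = s*eta - n*log(1+e^eta) - u^2/(2 sig^2) - log(sig sqrt(2 pi))
  nodes <- gh$x; wts <- log(gh$w)
  uu <- u + sqrt(2) * outer(tau, nodes)                    # accessions x nodes
  eta <- eta0 + uu
  lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))  # log(1 + e^eta)
  gval <- s * eta - n * lse - uu^2 / (2 * sig^2) - log(sig) -
    0.5 * log(2 * pi)
  gval <- sweep(gval, 2L, wts + nodes^2, `+`)
  ll <- log(sqrt(2) * tau) + row_logsumexp(gval)
  sum(ll) - sum(beta^2) / (2 * ridge_var)
}

# Fit the penalized logistic mixed model by BFGS over (beta, log sigma).
pav_fit <- function(s, n, X, gh, ridge_var) {
  p <- ncol(X)
  p0 <- min(max(sum(s) / sum(n), 0.02), 0.98)
  init <- c(qlogis(p0), rep(0, p - 1), 0)
  fn <- function(th) -pav_loglik(th, s, n, X, gh, ridge_var)
  opt <- tryCatch(optim(init, fn, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-12)),
                  error = function(e) NULL)
  if (is.null(opt)) {
    opt <- optim(init, fn, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  }
  list(loglik = -opt$value, beta = opt$par[seq_len(p)],
       sigma_a = exp(opt$par[p + 1]))
}

#' Presence-absence expression variation scan
#'
#' Per candidate gene, fits a random-intercept logistic model for the
#' expressed/not state with subspecies as fixed effect (symmetric +/- 0.5
#' coding) against the reduced model without it.  The accession random
#' intercept is integrated by adaptive Gauss-Hermite quadrature
#' (\code{nodes} points); a weak ridge penalty (Gaussian, variance
#' \code{ridge_var}) on the fixed effects, applied identically in both
#' fits, keeps estimates finite under complete separation.  LRT on 1 df.
#'
#' @param binary genes x samples 0/1 matrix (see \code{\link{encode_pav}}).
#' @param samples sample table.
#' @param assignment subspecies assignment.
#' @param genes gene ids to test (default: all rows of \code{binary}).
#' @param nodes Gauss-Hermite nodes (>= 9).
#' @param ridge_var ridge prior variance on fixed effects (default 25).
#' @param fdr significance threshold on q (default 0.001).
#' @return \code{divergence_result} data.frame (test = "PAV").
#' @export
pav_scan <- function(binary, samples, assignment, genes = rownames(binary),
                     nodes = 9, ridge_var = 25, fdr = 0.001) {
  if (nodes < 9) stopf("use at least 9 quadrature nodes")
  acc <- factor(samples$accession_id[match(colnames(binary), samples$sample_id)])
  ni <- as.vector(table(acc))
  S <- subspecies_code(levels(acc), assignment)
  Xf <- cbind(1, S); Xr <- cbind(rep(1, length(S)))
  gh <- pracma::gaussHermite(nodes)
  M <- stats::model.matrix(~ acc - 1)
  beta <- lrt <- p <- rep(NA_real_, length(genes))
  for (k in seq_along(genes)) {
    b <- binary[genes[k], ]
    s <- as.vector(b %*% M)
    full <- pav_fit(s, ni, Xf, gh, ridge_var)
    red <- pav_fit(s, ni, Xr, gh, ridge_var)
    lrt[k] <- max(0, 2 * (full$loglik - red$loglik))
    p[k] <- pchisq(lrt[k], df = 1, lower.tail = FALSE)
    beta[k] <- full$beta[2]
  }
  q <- bh_adjust(p)
  out <- data.frame(gene_id = genes, test = "PAV", beta = beta, mu = NA_real_,
                    lrt = lrt, p = p, q = q,
                    direction = ifelse(beta > 0, "higher-in-J", "higher-in-I"),
                    significant = !is.na(q) & q <= fdr,
                    stringsAsFactors = FALSE)
  class(out) <- c("divergence_result", "data.frame")
  out
}

#' PAV test for a single gene
#'
#' @param b named 0/1 vector over samples.
#' @inheritParams pav_scan
#' @return one-row \code{divergence_result} data.frame.
#' @export
fit_pav_gene <- function(b, samples, assignment, nodes = 9, ridge_var = 25) {
  m <- matrix(b, nrow = 1, dimnames = list("gene", names(b)))
  pav_scan(m, samples, assignment, nodes = nodes, ridge_var = ridge_var)[1, ]
}
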