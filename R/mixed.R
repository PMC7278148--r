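# One-way random-intercept likelihood machinery.
#
# The replicate-level model everywhere in this package is
#   y_ij = x_i' b + u_i + e_ij,   u_i ~ N(0, sigma_a^2), e_ij ~ N(0, sigma_e^2)
# with accession-level covariates x_i.  Its likelihood depends on the data
# only through per-accession means, per-accession within sums of squares and
# the group sizes, so per-gene fits reduce to a 1-D profile over
# rho = sigma_a^2 / sigma_e^2.  This is what makes genome-wide scans and
# permutation nulls affordable.

# Sufficient statistics for all genes at once.
# Y: genes x samples, acc: factor over samples.
oneway_stats <- function(Y, acc) {
  acc <- droplevels(acc)
  ni <- as.vector(table(acc))
  M <- stats::model.matrix(~ acc - 1)          # samples x a
  means <- Y %*% sweep(M, 2L, ni, `/`)         # genes x a
  ssw <- rowSums(Y^2) - as.vector(means^2 %*% ni)
  ssw <- pmax(ssw, 0)
  colnames(means) <- levels(acc)
  list(means = means, ssw = ssw, ni = ni, levels = levels(acc))
}

# -2 * restricted log-likelihood (up to an additive constant shared across
# rho) profiled over sigma_e^2 and the grand mean, for one gene.
m2ll_reml_oneway <- function(rho, m, ssw, ni) {
  w <- 1 + ni * rho
  v <- ni / w
  mu <- sum(v * m) / sum(v)
  Q <- max(ssw + sum(v * (m - mu)^2), 1e-300)
  N <- sum(ni)
  (N - 1) * log(Q / (N - 1)) + sum(log(w)) + log(sum(v)) + (N - 1)
}

# REML fit of the intercept-only one-way model from sufficient statistics.
reml_oneway <- function(m, ssw, ni) {
  f <- function(lr) m2ll_reml_oneway(exp(lr), m, ssw, ni)
  opt <- optimize(f, c(-30, 15))
  v0 <- m2ll_reml_oneway(0, m, ssw, ni)
  if (v0 <= opt$objective + 1e-10) {
    rho <- 0; obj <- v0
  } else {
    rho <- exp(opt$minimum); obj <- opt$objective
  }
  w <- 1 + ni * rho; v <- ni / w
  mu <- sum(v * m) / sum(v)
  N <- sum(ni)
  Q <- ssw + sum(v * (m - mu)^2)
  sigma_e2 <- Q / (N - 1)
  list(mu = mu, rho = rho, sigma_a2 = rho * sigma_e2, sigma_e2 = sigma_e2,
       H2 = rho / (1 + rho), rlrt = max(0, v0 - obj))
}

# Closed-form restricted LRT for the balanced design, vectorized over
# (SSB, SSW) pairs: non-zero only when MSB > MSW.
rlrt_balanced <- function(ssb, ssw, a, N) {
  msb <- ssb / (a - 1); msw <- ssw / (N - a)
  out <- (N - 1) * log((ssb + ssw) / (N - 1)) -
    (a - 1) * log(msb) - (N - a) * log(msw)
  out[msb <= msw] <- 0
  pmax(out, 0)
}

# -2 * ML log-likelihood profiled over sigma_e^2, with accession-level
# fixed-effect design X (a x p), for one gene.
m2ll_ml_oneway <- function(rho, m, ssw, ni, X) {
  w <- 1 + ni * rho
  v <- ni / w
  XtV <- X * v
  b <- tryCatch(solve(crossprod(XtV, X), crossprod(XtV, m)),
                error = function(e) rep(NA_real_, ncol(X)))
  if (anyNA(b)) return(Inf)
  r <- m - as.vector(X %*% b)
  Q <- max(ssw + sum(v * r^2), 1e-300)
  N <- sum(ni)
  list(val = N * log(Q / N) + sum(log(w)) + N, beta = as.vector(b))
}

# ML fit for a given fixed-effect design; returns the minimized deviance
# profile and coefficient estimates.
ml_oneway <- function(m, ssw, ni, X) {
  f <- function(lr) m2ll_ml_oneway(exp(lr), m, ssw, ni, X)$val
  opt <- optimize(f, c(-30, 15))
  v0 <- m2ll_ml_oneway(0, m, ssw, ni, X)
  if (v0$val <= opt$objective + 1e-10) {
    rho <- 0; obj <- v0$val
  } else {
    rho <- exp(opt$minimum); obj <- opt$objective
  }
  fit <- m2ll_ml_oneway(rho, m, ssw, ni, X)
  list(m2ll = obj, beta = fit$beta, rho = rho)
}
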