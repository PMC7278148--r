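test_that("broad-sense components recover the simulated variance split", {
  des <- make_design(a = 40L, r = 2L)
  y0 <- matrix(c(0, 0, 10, 10), 1,
               dimnames = list("g", paste0("s", 1:4)))
  s4 <- data.frame(sample_id = paste0("s", 1:4),
                   accession_id = rep(c("a1", "a2"), each = 2))
  expect_equal(fit_broad_h2(y0, s4)$H2, 1)

  set.seed(31)
  Ynull <- sim_oneway(200, des, sigma_a = 0, sigma_e = 1)
  expect_lt(mean(fit_broad_h2(Ynull, des$samples)$H2), 0.15)
  Yhalf <- sim_oneway(200, des, sigma_a = 1, sigma_e = 1)
  expect_lt(abs(mean(fit_broad_h2(Yhalf, des$samples)$H2) - 0.5), 0.05)

  # single replicate everywhere: components inseparable
  s1 <- data.frame(sample_id = paste0("s", 1:3),
                   accession_id = paste0("a", 1:3))
  y1 <- matrix(rnorm(3), 1, dimnames = list("g", s1$sample_id))
  expect_error(fit_broad_h2(y1, s1), "inseparable")
})

test_that("unbalanced REML agrees with lme4", {
  skip_if_not_installed("lme4")
  set.seed(32)
  ni <- c(2, 3, 2, 4, 2, 2, 3, 5, 2, 3)
  acc <- rep(sprintf("a%02d", seq_along(ni)), ni)
  y <- rep(rnorm(10), ni) + rnorm(length(acc))
  samples <- data.frame(sample_id = as.character(seq_along(y)),
                        accession_id = acc)
  Y <- matrix(y, 1, dimnames = list("g", samples$sample_id))
  fit <- fit_broad_h2(Y, samples)
  lfit <- lme4::lmer(y ~ (1 | acc), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$sigma_a2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma_e2, vc$vcov[2], tolerance = 1e-4)
})

test_that("the simulated restricted-LRT null shows boundary behavior", {
  null <- rlrt_null(rep(2L, 40L), B = 5000, seed = 3)
  expect_lt(abs(mean(null == 0) - 0.5), 0.05)   # half the mass at zero
  expect_equal(empirical_p(0, null), (1 + sum(null >= -1e-12)) / 5001)
  expect_gt(empirical_p(0, null), 0.95)
})

test_that("the GRM matches its closed-form construction", {
  g2 <- toy_genotypes(matrix(c(0, 1), 2, 1,
                             dimnames = list(c("a1", "a2"), NULL)))
  G <- build_grm(g2)
  expect_equal(unname(G$G), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)

  ds <- small_dataset()
  grm <- build_grm(ds$genotypes)
  expect_equal(mean(diag(grm$G)), 1, tolerance = 1e-12)
  expect_lt(max(abs(grm$G - t(grm$G))), 1e-10)
  expect_gt(min(eigen(grm$G, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  # swapping ref/alt coding of any SNP leaves G unchanged
  flip <- ds$genotypes
  flip$dosage[, 1:50] <- 1 - flip$dosage[, 1:50]
  expect_equal(build_grm(flip)$G, grm$G, tolerance = 1e-12)
})

# Dense generalized-least-squares REML log-likelihood, written from the
# definition (inverse and determinants of the full covariance), as an
# independent oracle for the spectral profile.
dense_reml_loglik <- function(y, G, lambda) {
  n <- length(y)
  V <- lambda * G + diag(n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  XtVX <- t(X) %*% Vi %*% X
  b <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  Q <- as.numeric(t(r) %*% Vi %*% r)
  s2 <- Q / (n - 1)
  -0.5 * ((n - 1) * log(s2) + determinant(V)$modulus + log(det(XtVX)) +
            (n - 1))
}

test_that("spectral GRM-REML equals a dense GLS likelihood evaluation", {
  set.seed(33)
  g <- toy_genotypes(matrix(rbinom(8 * 60, 1, 0.4), 8, 60,
                            dimnames = list(paste0("a", 1:8), NULL)))
  grm <- build_grm(g)
  y <- as.vector(chol(grm$G + diag(8) * 0.5) %*% rnorm(8)) |> drop()
  names(y) <- paste0("a", 1:8)
  e <- eigen(grm$G, symmetric = TRUE)
  yt <- as.vector(t(e$vectors) %*% y)
  xt <- as.vector(t(e$vectors) %*% rep(1, 8))
  for (lam in c(0, 0.1, 1, 5, 50)) {
    mine <- -0.5 * oryzadiv:::m2ll_reml_grm(lam, yt, xt, pmax(e$values, 0))
    expect_equal(mine, as.numeric(dense_reml_loglik(y, grm$G, lam)),
                 tolerance = 1e-6)
  }
})

test_that("narrow-sense fits hit the boundary on noiseless data", {
  ds <- small_dataset()
  grm <- build_grm(ds$genotypes)
  e <- eigen(grm$G, symmetric = TRUE)
  y <- matrix(e$vectors[, 1], 1, dimnames = list("g", grm$accessions))
  fit <- fit_narrow_h2(y, grm)
  expect_gte(fit$h2, 0.99)
  # and stays in [0, 1] on pure noise
  set.seed(34)
  Y0 <- matrix(rnorm(50 * nrow(grm$G)), 50,
               dimnames = list(paste0("g", 1:50), grm$accessions))
  f0 <- fit_narrow_h2(Y0, grm)
  expect_true(all(f0$h2 >= 0 & f0$h2 <= 1))
  expect_true(all(f0$lrt >= 0))
})

test_that("within-subspecies fits find subspecies-specific genetic control", {
  cfg <- sim_config(n_accessions_per_pop = c(I = 25L, J = 30L),
                    n_snps = 2500L, n_genes = 60L,
                    architecture_mix = c(null = 0.5, eqtl_I = 0.5),
                    target_h2 = 0.6,
                    chromosome_lengths = setNames(rep(12e6, 2),
                                                  c("chr01", "chr02")),
                    seed = 77L)
  ds <- simulate_dataset(cfg)
  asg <- setNames(ds$pops, names(ds$pops))
  class(asg) <- "subspecies_assignment"
  # (constant genes inside one subspecies warn about random INT ranks)
  w <- suppressWarnings(
    within_subspecies_h2(ds$counts, ds$samples, ds$genotypes, asg,
                         seed = 3L, B_null = 2000))
  expect_identical(length(w$I$accessions), length(w$J$accessions))
  eq_genes <- ds$truth$gene_id[ds$truth$class == "eqtl_I"]
  HI <- w$I$broad$H2[match(eq_genes, w$I$broad$gene_id)]
  HJ <- w$J$broad$H2[match(eq_genes, w$J$broad$gene_id)]
  # the cis effect is masked in J, so total accession-level (broad-sense)
  # heritability is higher in I for these genes
  expect_gt(mean(HI, na.rm = TRUE), mean(HJ, na.rm = TRUE) + 0.08)
  # while null genes show no such asymmetry
  null_genes <- ds$truth$gene_id[ds$truth$class == "null"]
  NI <- w$I$broad$H2[match(null_genes, w$I$broad$gene_id)]
  NJ <- w$J$broad$H2[match(null_genes, w$J$broad$gene_id)]
  expect_lt(abs(mean(NI, na.rm = TRUE) - mean(NJ, na.rm = TRUE)), 0.08)
})

test_that("heritability-difference permutation is exact in its edge cases", {
  des <- make_design(a = 70L, r = 2L)
  set.seed(36)
  Y <- sim_oneway(5, des, sigma_a = 1, sigma_e = 1)
  d0 <- setNames(rep(0, 5), rownames(Y))
  res <- delta_h_permutation(d0, kind = "broad", expr = Y,
                             samples = des$samples, group_size = 35L,
                             B = 20, seed = 4)
  expect_true(all(res$p == 1))   # |delta_null| >= 0 always
  expect_error(delta_h_permutation(d0, kind = "broad", expr = Y,
                                   samples = des$samples, group_size = 35L,
                                   B = 0, seed = 4), "B must")
  # seeded runs repeat identically
  d1 <- setNames(runif(5, -0.3, 0.3), rownames(Y))
  r1 <- delta_h_permutation(d1, kind = "broad", expr = Y,
                            samples = des$samples, group_size = 30L,
                            B = 30, seed = 9)
  r2 <- delta_h_permutation(d1, kind = "broad", expr = Y,
                            samples = des$samples, group_size = 30L,
                            B = 30, seed = 9)
  expect_identical(r1$p, r2$p)
})
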