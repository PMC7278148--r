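# Brute-force Hudson Fst estimator: ratio of averages over per-SNP
# numerators/denominators computed from allele counts from first principles.
hudson_oracle <- function(d1, d2) {
  num <- den <- 0
  for (j in seq_len(ncol(d1))) {
    x1 <- d1[, j][!is.na(d1[, j])]; x2 <- d2[, j][!is.na(d2[, j])]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(x1); p2 <- mean(x2)
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

test_that("genotype simulation hits the requested divergence", {
  # no-divergence limit
  cfg0 <- sim_config(n_accessions_per_pop = c(I = 40L, J = 40L), n_snps = 2000L,
                     n_genes = 10L, fst_per_pop = c(I = 1e-6, J = 1e-6),
                     chromosome_lengths = c(chr01 = 5e6), seed = 5L)
  g0 <- simulate_genotypes(cfg0)
  expect_lt(abs(fst_hudson(g0$genotypes, g0$pops)), 0.02)

  # F = 0.4 per population: package estimate equals the brute-force oracle,
  # and the realized divergence lands near the Balding-Nichols parameter
  cfg <- sim_config(n_accessions_per_pop = c(I = 50L, J = 50L), n_snps = 5000L,
                    n_genes = 10L, fst_per_pop = c(I = 0.4, J = 0.4),
                    chromosome_lengths = c(chr01 = 10e6), seed = 6L)
  g <- simulate_genotypes(cfg)
  d <- g$genotypes$dosage
  ora <- hudson_oracle(d[g$pops == "I", ], d[g$pops == "J", ])
  expect_equal(fst_hudson(g$genotypes, g$pops), ora, tolerance = 1e-12)
  expect_lt(abs(ora - 0.4), 0.05)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_accessions_per_pop = c(I = 8L, J = 8L), n_snps = 300L,
                    n_genes = 30L, chromosome_lengths = c(chr01 = 2e6),
                    seed = 42L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genotypes$dosage, d2$genotypes$dosage)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth, d2$truth)
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(architecture_mix = c(null = 0.5, de = 0.4)), "sum to 1")
  expect_error(sim_config(fst_per_pop = c(I = 0, J = 0.4)), "open interval")
  expect_error(sim_config(chromosome_lengths = c(chr01 = 0)), "zero-length")
})

test_that("inject_sweep drives the target population to near-fixation", {
  ds <- small_dataset()
  gt <- ds$genotypes
  reg <- data.frame(chrom = "chr01", start = 1e6, end = 2e6, target_pop = "J",
                    stringsAsFactors = FALSE)
  swept <- inject_sweep(gt, reg, ds$pops)
  in_reg <- which(gt$snps$chrom == "chr01" & gt$snps$pos >= 1e6 &
                    gt$snps$pos <= 2e6)
  expect_gt(length(in_reg), 0)
  dJ <- swept$dosage[ds$pops == "J", in_reg, drop = FALSE]
  minor <- apply(dJ, 2L, function(x) min(sum(x == 0, na.rm = TRUE),
                                         sum(x == 1, na.rm = TRUE)))
  expect_true(all(minor <= 1))
  # non-target population untouched, outside region untouched
  expect_identical(swept$dosage[ds$pops == "I", ], gt$dosage[ds$pops == "I", ])
  expect_identical(swept$dosage[, -in_reg], gt$dosage[, -in_reg])
  # swept window pi (direct site-pi computation) below target-pop genome mean
  pi_of <- function(d) {
    na <- colSums(d, na.rm = TRUE); n <- colSums(!is.na(d))
    mean(site_pi(n - na, na), na.rm = TRUE)
  }
  expect_lt(pi_of(swept$dosage[ds$pops == "J", in_reg, drop = FALSE]),
            pi_of(swept$dosage[ds$pops == "J", -in_reg, drop = FALSE]))
  # empty region: warning, no-op
  empty <- data.frame(chrom = "chr02", start = 1, end = 10, target_pop = "J")
  expect_warning(out <- inject_sweep(gt, empty, ds$pops), "no SNPs")
  expect_identical(out$dosage, gt$dosage)
})

test_that("architectures honour the class mix and heritability target", {
  cfg <- sim_config(n_accessions_per_pop = c(I = 30L, J = 30L), n_snps = 1500L,
                    n_genes = 100L, architecture_mix = c(null = 1),
                    chromosome_lengths = c(chr01 = 6e6), seed = 9L)
  geno <- simulate_genotypes(cfg)
  arch <- simulate_architecture(cfg, geno)
  expect_true(all(arch$table$class == "null"))

  cfg2 <- sim_config(n_accessions_per_pop = c(I = 30L, J = 30L), n_snps = 1500L,
                     n_genes = 100L, architecture_mix = c(heritable = 1),
                     target_h2 = 0.5,
                     chromosome_lengths = c(chr01 = 6e6), seed = 10L)
  arch2 <- simulate_architecture(cfg2, simulate_genotypes(cfg2))
  # realized genetic variance fraction of the accession-level predictor
  gvar <- apply(arch2$genetic, 1L, var)
  tvar <- apply(arch2$eta, 1L, var)
  expect_lt(mean(abs(gvar / tvar - 0.5)), 0.05)

  cfg3 <- sim_config(n_accessions_per_pop = c(I = 30L, J = 30L), n_snps = 1500L,
                     n_genes = 60L, architecture_mix = c(eqtl_I = 1),
                     chromosome_lengths = c(chr01 = 6e6), seed = 11L)
  geno3 <- simulate_genotypes(cfg3)
  arch3 <- simulate_architecture(cfg3, geno3)
  eq <- arch3$table[arch3$table$class == "eqtl_I", ]
  expect_true(all(eq$cis_active_I) && !any(eq$cis_active_J))
  # cis SNP lies inside the 100 kb window of the gene's TSS
  snp_pos <- geno3$genotypes$snps$pos[match(eq$cis_snp_id,
                                            geno3$genotypes$snps$snp_id)]
  tss <- arch3$genes$tss[match(eq$gene_id, arch3$genes$gene_id)]
  expect_true(all(abs(snp_pos - tss) <= 1e5))
})

test_that("count model matches its moments", {
  ds <- small_dataset()
  expect_true(all(ds$counts >= 0))
  expect_identical(storage.mode(ds$counts), "integer")

  # Poisson limit: phi = Inf, size factors 1, constant mean
  cfg <- sim_config(n_accessions_per_pop = c(I = 25L, J = 25L), n_snps = 200L,
                    n_genes = 50L, architecture_mix = c(null = 1),
                    nb_dispersion = Inf, size_factor_range = c(1, 1),
                    acc_var = 1e-12,
                    chromosome_lengths = c(chr01 = 1e6), seed = 13L)
  ds2 <- simulate_dataset(cfg)
  mu <- exp(ds2$truth$baseline_log_mean)
  obs <- rowMeans(ds2$counts)
  N <- ncol(ds2$counts)
  expect_true(all(abs(obs - mu) < 3 * sqrt(mu / N) + 1e-9))

  # DE gene with delta = 2 (natural log): pop log2-ratio ~ 2/ln 2 on the
  # normalized scale, recomputed from the generated matrix
  cfg3 <- sim_config(n_accessions_per_pop = c(I = 40L, J = 40L), n_snps = 200L,
                     n_genes = 60L, architecture_mix = c(de = 1), de_shift = 2,
                     acc_var = 0.05, size_factor_range = c(1, 1),
                     chromosome_lengths = c(chr01 = 1e6), seed = 14L)
  ds3 <- simulate_dataset(cfg3)
  v <- normalize_vst(ds3$counts)
  pop <- ds3$pops[ds3$samples$accession_id]
  lr <- rowMeans(v[, pop == "J"]) - rowMeans(v[, pop == "I"])
  sgn <- sign(ds3$truth$de_shift)
  expect_equal(mean(lr * sgn), 2 / log(2), tolerance = 0.12)
})
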