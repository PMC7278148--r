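# Shared fixtures, built in code.  The cache keeps one small simulated panel
# per configuration so independent test files do not pay for re-simulation.

.fixtures <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(n_accessions_per_pop = c(I = 15L, J = 20L),
                      n_snps = 2000L, n_genes = 120L,
                      chromosome_lengths = setNames(rep(8e6, 3),
                                                    sprintf("chr%02d", 1:3)),
                      seed = 101L)
    .fixtures$small <- simulate_dataset(cfg)
  }
  .fixtures$small
}

# balanced replicate design: a accessions x r replicates, split half I half J
make_design <- function(a = 70L, r = 2L) {
  acc <- sprintf("acc%03d", seq_len(a))
  samples <- data.frame(sample_id = paste0("s", seq_len(a * r)),
                        accession_id = rep(acc, each = r),
                        replicate = rep(seq_len(r), a),
                        stringsAsFactors = FALSE)
  asg <- setNames(rep(c("I", "J"), each = a / 2), acc)
  class(asg) <- "subspecies_assignment"
  list(samples = samples, assignment = asg, acc = acc, a = a, r = r)
}

# genes x samples matrix of one-way gaussian data with given variance split
sim_oneway <- function(n_genes, design, sigma_a = 1, sigma_e = 1, beta = 0) {
  a <- design$a; r <- design$r
  S <- rep(ifelse(unclass(design$assignment)[design$samples$accession_id] == "J",
                  0.5, -0.5), 1)
  Y <- t(vapply(seq_len(n_genes), function(g) {
    rep(rnorm(a, 0, sigma_a), each = r) + rnorm(a * r, 0, sigma_e) + beta * S
  }, numeric(a * r)))
  rownames(Y) <- sprintf("g%04d", seq_len(n_genes))
  colnames(Y) <- design$samples$sample_id
  Y
}

# small genotype_table built directly from a dosage matrix
toy_genotypes <- function(dosage, chrom = "chr01", pos = NULL) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = m)
  snp_id <- sprintf("%s_%06d", chrom, pos)
  colnames(dosage) <- snp_id
  snps <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  genotype_table(dosage, snps)
}
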