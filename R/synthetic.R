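#' Simulation configuration for the synthetic rice panel
#'
#' Bundles the parameters of the synthetic two-subspecies panel: a
#' Balding-Nichols genotype model for the Indica-like ("I") and Japonica-like
#' ("J") subpopulations, gene architectures (differential expression,
#' presence-absence variation, polygenic heritability, subspecies-specific
#' cis-eQTL), and negative-binomial replicate-level read counts.
#'
#' The defaults mirror the study design the package emulates: 35 + 56
#' accessions, two biological replicates each, a strongly divergent pair of
#' subpopulations with asymmetric drift (F_I = 0.30, F_J = 0.55, giving
#' Hudson Fst near 0.4 and a Japonica-to-Indica within-group diversity
#' ratio near the 0.65 observed in rice), and a 12-chromosome genome.
#'
#' @param n_accessions_per_pop named integer vector \code{c(I=,J=)}.
#' @param n_replicates replicates per accession (default 2).
#' @param n_snps total SNP count, spread over chromosomes by length.
#' @param n_genes number of genes.
#' @param chromosome_lengths named vector of chromosome lengths (bp).
#' @param fst_per_pop named divergence parameter F per subpopulation, each in
#'   (0, 1): the Balding-Nichols drift from the shared ancestral frequency.
#' @param nb_dispersion negative-binomial dispersion phi (> 0); counts have
#'   Var = mu + mu^2/phi.  \code{Inf} gives Poisson counts.
#' @param size_factor_range interval for per-sample library size factors.
#' @param architecture_mix named proportions over gene classes
#'   \code{null, de, pav, heritable, eqtl_I, eqtl_J, eqtl_both}; must sum to 1.
#' @param sweep_regions optional data.frame (chrom, start, end, target_pop)
#'   of regions driven to near-fixation in one subpopulation.
#' @param acc_var total accession-level variance of log expression (genetic +
#'   accession environment), natural-log scale.
#' @param de_shift magnitude of the natural-log subspecies shift for "de" genes.
#' @param pav_logit_shift magnitude of the subspecies shift on the logit of
#'   the expression-on probability for "pav" genes.
#' @param target_h2 accession-level genetic variance fraction for heritable
#'   and eQTL gene classes, in [0, 1).
#' @param seed integer seed; every draw in the generator flows from it.
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_accessions_per_pop = c(I = 35L, J = 56L),
                       n_replicates = 2L,
                       n_snps = 20000L,
                       n_genes = 1000L,
                       chromosome_lengths = setNames(rep(30e6, 12),
                                                     sprintf("chr%02d", 1:12)),
                       fst_per_pop = c(I = 0.30, J = 0.55),
                       nb_dispersion = 10,
                       size_factor_range = c(0.7, 1.4),
                       architecture_mix = c(null = 0.40, de = 0.15, pav = 0.10,
                                            heritable = 0.15, eqtl_I = 0.05,
                                            eqtl_J = 0.05, eqtl_both = 0.10),
                       sweep_regions = NULL,
                       acc_var = 0.25,
                       de_shift = 1,
                       pav_logit_shift = 2,
                       target_h2 = 0.4,
                       seed = 1L) {
  classes <- c("null", "de", "pav", "heritable", "eqtl_I", "eqtl_J", "eqtl_both")
  mix <- architecture_mix
  if (is.null(names(mix)) || !all(names(mix) %in% classes))
    stopf("architecture_mix names must be among: %s", paste(classes, collapse = ", "))
  full <- setNames(numeric(length(classes)), classes)
  full[names(mix)] <- mix
  if (abs(sum(full) - 1) > 1e-9) stopf("architecture_mix must sum to 1")
  if (any(full < 0)) stopf("architecture_mix proportions must be >= 0")
  if (any(n_accessions_per_pop < 1) || n_replicates < 1 || n_snps < 1 || n_genes < 1)
    stopf("all counts must be positive")
  if (any(fst_per_pop <= 0 | fst_per_pop >= 1))
    stopf("fst_per_pop must lie in the open interval (0, 1)")
  if (any(chromosome_lengths <= 0)) stopf("zero-length chromosome rejected")
  if (!(nb_dispersion > 0)) stopf("nb_dispersion must be > 0")
  if (target_h2 < 0 || target_h2 >= 1) stopf("target_h2 must be in [0, 1)")
  if (!is.null(sweep_regions)) {
    need <- c("chrom", "start", "end", "target_pop")
    if (!all(need %in% names(sweep_regions))) stopf("sweep_regions needs columns %s",
                                                    paste(need, collapse = ", "))
  }
  structure(list(
    n_accessions_per_pop = setNames(as.integer(n_accessions_per_pop),
                                    names(n_accessions_per_pop)),
    n_replicates = as.integer(n_replicates),
    n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
    chromosome_lengths = chromosome_lengths,
    fst_per_pop = fst_per_pop, nb_dispersion = nb_dispersion,
    size_factor_range = size_factor_range, architecture_mix = full,
    sweep_regions = sweep_regions, acc_var = acc_var, de_shift = de_shift,
    pav_logit_shift = pav_logit_shift, target_h2 = target_h2,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate genotypes under a two-population Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.95); each
#' subpopulation k draws its frequency from
#' Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k) and inbred accessions draw a haploid
#' dosage Bernoulli(p_k).  SNP positions are uniform over chromosomes
#' (proportional allocation by length) and sorted.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{genotypes} (a
#'   \code{\link{genotype_table}}) and \code{pops} (named vector
#'   accession -> subpopulation label).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 101L), {
    lens <- config$chromosome_lengths
    n_chr <- length(lens)
    alloc <- floor(config$n_snps * lens / sum(lens))
    rem <- config$n_snps - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
    pops_n <- config$n_accessions_per_pop
    acc <- unlist(lapply(names(pops_n), function(k)
      sprintf("%s_%03d", k, seq_len(pops_n[[k]]))))
    pops <- setNames(rep(names(pops_n), pops_n), acc)
    n_acc <- length(acc)

    chrom <- rep(names(lens), alloc)
    pos <- unlist(lapply(seq_len(n_chr), function(i)
      sort(sample.int(lens[i], alloc[i]))))
    m <- length(pos)
    snp_id <- sprintf("%s_%09d", chrom, pos)
    p_anc <- runif(m, 0.05, 0.95)
    dosage <- matrix(NA_real_, n_acc, m, dimnames = list(acc, snp_id))
    for (k in names(pops_n)) {
      Fk <- config$fst_per_pop[[k]]
      a <- p_anc * (1 - Fk) / Fk
      b <- (1 - p_anc) * (1 - Fk) / Fk
      pk <- rbeta(m, a, b)
      idx <- which(pops == k)
      dosage[idx, ] <- matrix(rbinom(length(idx) * m, 1L, rep(pk, each = length(idx))),
                              nrow = length(idx))
    }
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
    snps <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                       ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
    list(genotypes = genotype_table(dosage, snps), pops = pops)
  })
}

#' Drive regions to near-fixation in one subpopulation
#'
#' Emulates a selective sweep: inside each region, the target subpopulation's
#' dosages are overwritten so the minor-allele count is at most 1 (all
#' accessions take the current within-group major allele; the first carrier
#' of the minor allele, if any, is left in place).  Other subpopulations are
#' untouched.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param regions data.frame (chrom, start, end, target_pop), closed intervals.
#' @param pops named accession -> subpopulation vector.
#' @return the modified \code{genotype_table}.
#' @export
inject_sweep <- function(gt, regions, pops) {
  d <- gt$dosage
  pops <- pops[rownames(d)]
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (!r$chrom %in% gt$snps$chrom) stopf("sweep region on unknown chromosome %s", r$chrom)
    idx <- which(gt$snps$chrom == r$chrom & gt$snps$pos >= r$start & gt$snps$pos <= r$end)
    if (!length(idx)) {
      warnf("sweep region %s:%d-%d contains no SNPs; skipped", r$chrom, r$start, r$end)
      next
    }
    rows <- which(pops == r$target_pop)
    for (j in idx) {
      x <- d[rows, j]
      obs <- !is.na(x)
      if (!sum(obs)) next
      major <- as.numeric(mean(x[obs]) >= 0.5)
      minor_at <- which(obs & x != major)
      x[obs] <- major
      if (length(minor_at)) x[minor_at[1L]] <- 1 - major
      d[rows, j] <- x
    }
  }
  structure(list(dosage = d, snps = gt$snps), class = "genotype_table")
}

#' Assign gene positions and regulatory architectures
#'
#' Places genes uniformly on the chromosomes, draws a class for each gene
#' from \code{architecture_mix}, and builds the accession-level expression
#' predictor: baseline log-mean b0, subspecies shift (de), expression-on
#' probability shift (pav), polygenic genetic values (heritable) or a single
#' cis SNP effect active in one or both subspecies (eqtl_I / eqtl_J /
#' eqtl_both).  Genetic values are rescaled so the accession-level genetic
#' variance fraction equals \code{target_h2}; the remaining accession
#' variance is non-genetic.  eQTL classes with no cis SNP of pooled MAF >=
#' 0.1 within 100 kb of the TSS are reassigned to "heritable" with a message.
#'
#' @param config a \code{\link{sim_config}}.
#' @param geno output of \code{\link{simulate_genotypes}} (list with
#'   \code{genotypes} and \code{pops}).
#' @return object of class \code{gene_architecture}: list with \code{table}
#'   (per-gene truth), \code{genes} (gene annotation), \code{eta}
#'   (genes x accessions accession-level log-mean predictor), \code{genetic}
#'   (genes x accessions genetic values) and \code{on_prob}
#'   (genes x accessions expression-on probability, 1 except for pav genes).
#' @export
simulate_architecture <- function(config, geno) {
  stopifnot(inherits(config, "sim_config"))
  gt <- geno$genotypes; pops <- geno$pops
  acc <- rownames(gt$dosage); n_acc <- length(acc)
  with_seed(derive_seed(config$seed, 202L), {
    lens <- config$chromosome_lengths
    g_chr <- sample(names(lens), config$n_genes, replace = TRUE,
                    prob = lens / sum(lens))
    g_tss <- vapply(g_chr, function(ch) sample.int(lens[[ch]], 1L), integer(1))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    gene_id <- sprintf("gene_%04d", seq_len(config$n_genes))
    genes <- data.frame(gene_id = gene_id, chrom = g_chr, tss = g_tss,
                        strand = strand, stringsAsFactors = FALSE)

    cls <- sample(names(config$architecture_mix), config$n_genes, replace = TRUE,
                  prob = config$architecture_mix)
    maf_pool <- snp_maf(gt)
    maf_by <- snp_maf(gt, pops)
    sd_acc <- sqrt(config$acc_var)
    is_I <- pops[acc] == "I"

    b0 <- runif(config$n_genes, log(20), log(2000))
    de_shift <- numeric(config$n_genes)
    pav_shift <- numeric(config$n_genes)
    h2 <- numeric(config$n_genes)
    cis_snp <- rep(NA_character_, config$n_genes)
    cis_eff <- rep(NA_real_, config$n_genes)
    act_I <- rep(NA, config$n_genes); act_J <- rep(NA, config$n_genes)

    genetic <- matrix(0, config$n_genes, n_acc, dimnames = list(gene_id, acc))
    on_prob <- matrix(1, config$n_genes, n_acc, dimnames = list(gene_id, acc))

    scale_to <- function(g, v_target) {
      s <- sd(g)
      if (s < 1e-12) return(rep(0, length(g)))
      (g - mean(g)) / s * sqrt(v_target)
    }

    for (i in seq_len(config$n_genes)) {
      ci <- cls[i]
      if (ci %in% c("eqtl_I", "eqtl_J", "eqtl_both")) {
        # the cis SNP must segregate in every subspecies in which the
        # effect is active, or the architecture would not be realizable
        ok_pop <- switch(ci,
                         eqtl_I = maf_by["I", ] >= 0.1,
                         eqtl_J = maf_by["J", ] >= 0.1,
                         eqtl_both = maf_by["I", ] >= 0.1 & maf_by["J", ] >= 0.1)
        cand <- which(gt$snps$chrom == g_chr[i] &
                        abs(gt$snps$pos - g_tss[i]) <= 1e5 & maf_pool >= 0.1 &
                        ok_pop)
        if (!length(cand)) {
          message(sprintf("gene %s: no cis SNP available; class %s -> heritable",
                          gene_id[i], ci))
          ci <- cls[i] <- "heritable"
        }
      }
      if (ci == "de") {
        de_shift[i] <- sample(c(-1, 1), 1L) * config$de_shift
      } else if (ci == "pav") {
        pav_shift[i] <- sample(c(-1, 1), 1L) * config$pav_logit_shift
        base <- qlogis(runif(1, 0.35, 0.65))
        eta_on <- base + pav_shift[i] * as.numeric(!is_I)  # shift applies to J
        on_prob[i, ] <- plogis(eta_on)
      } else if (ci == "heritable") {
        h2[i] <- config$target_h2
        k <- min(100L, ncol(gt$dosage))
        sel <- sample.int(ncol(gt$dosage), k)
        eff <- rnorm(k)
        gval <- as.numeric(gt$dosage[, sel, drop = FALSE] %*% eff)
        genetic[i, ] <- scale_to(gval, h2[i] * config$acc_var)
      } else if (ci %in% c("eqtl_I", "eqtl_J", "eqtl_both")) {
        h2[i] <- config$target_h2
        j <- cand[sample.int(length(cand), 1L)]
        cis_snp[i] <- gt$snps$snp_id[j]
        act_I[i] <- ci %in% c("eqtl_I", "eqtl_both")
        act_J[i] <- ci %in% c("eqtl_J", "eqtl_both")
        mask <- (is_I & act_I[i]) | (!is_I & act_J[i])
        x <- gt$dosage[, j]
        x[is.na(x)] <- mean(x, na.rm = TRUE)
        # scale so the variance fraction within the active subspecies equals h2
        xa <- x[mask]
        s <- sd(xa)
        beta <- if (s < 1e-12) 0 else sqrt(h2[i] * config$acc_var) / s
        cis_eff[i] <- beta
        g <- numeric(n_acc)
        g[mask] <- beta * (x[mask] - mean(xa))
        genetic[i, ] <- g
      }
      if (ci %in% c("eqtl_I", "eqtl_J", "eqtl_both", "heritable")) {
        # orthogonalize and rescale the non-genetic accession effect so the
        # realized genetic variance fraction matches target_h2
        env <- rnorm(n_acc)
        g <- genetic[i, ]
        if (sd(g) > 1e-12) env <- env - g * sum(env * (g - mean(g))) / sum((g - mean(g))^2)
        env <- scale_to(env, (1 - h2[i]) * config$acc_var)
      } else {
        env <- rnorm(n_acc, 0, sqrt(config$acc_var))
      }
      eta_i <- b0[i] + genetic[i, ] + env + de_shift[i] * as.numeric(!is_I)
      genetic[i, ] <- genetic[i, ]  # kept as ground truth
      if (i == 1L) eta <- matrix(0, config$n_genes, n_acc, dimnames = list(gene_id, acc))
      eta[i, ] <- eta_i
    }

    tab <- data.frame(gene_id = gene_id, class = cls, de_shift = de_shift,
                      pav_logit_shift = pav_shift, target_h2 = h2,
                      cis_snp_id = cis_snp, cis_effect = cis_eff,
                      cis_active_I = act_I, cis_active_J = act_J,
                      baseline_log_mean = b0, stringsAsFactors = FALSE)
    structure(list(table = tab, genes = genes, eta = eta, genetic = genetic,
                   on_prob = on_prob, pops = pops),
              class = "gene_architecture")
  })
}

#' @export
print.gene_architecture <- function(x, ...) {
  cat(sprintf("gene_architecture: %d genes\n", nrow(x$table)))
  print(table(x$table$class))
  invisible(x)
}

#' Simulate replicate-level RNA-seq read counts
#'
#' Counts for gene g, accession i, replicate j are negative binomial with
#' mean \eqn{s_j \exp(\eta_{gi})} and dispersion phi
#' (Var = mu + mu^2/phi); \code{nb_dispersion = Inf} gives Poisson counts.
#' For pav genes an accession first draws an on/off state from its
#' expression-on probability; off accessions emit Poisson(0.1) background.
#'
#' @param arch a \code{gene_architecture} from
#'   \code{\link{simulate_architecture}}.
#' @param config the \code{\link{sim_config}} used throughout.
#' @return list: \code{counts} (integer genes x samples matrix),
#'   \code{samples} (sample metadata with subspecies truth),
#'   \code{size_factors}, \code{on_state} (genes x accessions logical).
#' @export
simulate_counts <- function(arch, config) {
  stopifnot(inherits(arch, "gene_architecture"), inherits(config, "sim_config"))
  acc <- colnames(arch$eta); n_acc <- length(acc)
  r <- config$n_replicates
  with_seed(derive_seed(config$seed, 303L), {
    samples <- data.frame(
      sample_id = as.vector(t(outer(acc, seq_len(r), function(a, k)
        sprintf("%s_r%d", a, k)))),
      accession_id = rep(acc, each = r),
      replicate = rep(seq_len(r), times = n_acc),
      subspecies = rep(unname(arch$pops[acc]), each = r),
      stringsAsFactors = FALSE)
    n_s <- nrow(samples)
    sf <- runif(n_s, config$size_factor_range[1], config$size_factor_range[2])
    on_state <- matrix(rbinom(length(arch$on_prob), 1L, arch$on_prob) == 1L,
                       nrow(arch$on_prob), ncol(arch$on_prob),
                       dimnames = dimnames(arch$on_prob))
    mu_acc <- exp(arch$eta)            # genes x accessions
    mu_acc[!on_state] <- NA            # off -> background Poisson(0.1)
    if (any(!is.finite(arch$eta))) {
      bad <- rownames(arch$eta)[!is.finite(rowSums(arch$eta))][1]
      stopf("non-finite expression mean for gene %s", bad)
    }
    mu <- mu_acc[, samples$accession_id, drop = FALSE]
    mu <- sweep(mu, 2L, sf, `*`)
    counts <- matrix(0L, nrow(mu), ncol(mu),
                     dimnames = list(rownames(mu), samples$sample_id))
    off <- is.na(mu)
    if (is.finite(config$nb_dispersion)) {
      counts[!off] <- rnbinom(sum(!off), size = config$nb_dispersion, mu = mu[!off])
    } else {
      counts[!off] <- rpois(sum(!off), mu[!off])
    }
    counts[off] <- rpois(sum(off), 0.1)
    storage.mode(counts) <- "integer"
    list(counts = counts, samples = samples, size_factors = sf, on_state = on_state)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs \code{\link{simulate_genotypes}}, optional
#' \code{\link{inject_sweep}}, \code{\link{simulate_architecture}} and
#' \code{\link{simulate_counts}} under the config's seed and bundles the
#' pieces into the dataset shape the analysis stages consume.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{rice_dataset}: list with \code{genotypes},
#'   \code{counts}, \code{genes}, \code{samples}, \code{truth}
#'   (architecture table), \code{pops}, \code{arch} (full architecture
#'   object) and \code{config}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  if (!is.null(config$sweep_regions))
    geno$genotypes <- inject_sweep(geno$genotypes, config$sweep_regions, geno$pops)
  arch <- simulate_architecture(config, geno)
  cnt <- simulate_counts(arch, config)
  structure(list(genotypes = geno$genotypes, counts = cnt$counts,
                 genes = arch$genes, samples = cnt$samples,
                 truth = arch$table, pops = geno$pops, arch = arch,
                 size_factors = cnt$size_factors, config = config),
            class = "rice_dataset")
}

#' @export
print.rice_dataset <- function(x, ...) {
  cat(sprintf("rice_dataset: %d accessions (%s), %d samples, %d genes, %d SNPs\n",
              nrow(x$genotypes$dosage),
              paste(sprintf("%s=%d", names(table(x$pops)), table(x$pops)), collapse = ", "),
              nrow(x$samples), nrow(x$genes), ncol(x$genotypes$dosage)))
  invisible(x)
}
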