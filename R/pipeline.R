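#' Run the full transcriptome-divergence pipeline on a synthetic panel
#'
#' simulate -> preprocess (filter, normalize, INT, genotype PCA, subspecies
#' classification) -> divergence (DE + PAV) -> diversity (CV, site-pi) ->
#' heritability (broad + narrow, across and within subspecies) -> delta-H2 /
#' delta-h2 permutation -> joint cis-eQTL scan -> selection scan.  Every
#' stage is seeded from \code{config$seed}, so two runs with the same config
#' are bit-identical.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir optional directory; when given, all result tables are
#'   written as TSV via \code{\link{write_results}}.
#' @param B_eqtl permutations per gene in the eQTL scan.
#' @param B_delta permutation rounds for the heritability-difference test.
#' @param B_rlrt draws for the broad-sense restricted-LRT null.
#' @param fdr_divergence,fdr_h2,fdr_eqtl significance thresholds.
#' @param h2_filter restrict the eQTL scan to genes with significant
#'   broad-sense heritability in at least one subspecies (default TRUE).
#' @param delta_genes optional cap on the number of genes entering the
#'   narrow-sense delta-h2 permutation (NULL = all shared genes).
#' @param force overwrite existing TSVs in \code{out_dir}.
#' @return object of class \code{oryzadiv_pipeline}: a list with every
#'   stage's results and the tables written.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         B_eqtl = 1000, B_delta = 100, B_rlrt = 10000,
                         fdr_divergence = 0.001, fdr_h2 = 0.001,
                         fdr_eqtl = 0.05, h2_filter = TRUE,
                         delta_genes = NULL, force = FALSE) {
  seed <- config$seed
  ds <- simulate_dataset(config)

  ## preprocess
  pca <- genotype_pca(ds$genotypes, maf_min = 0.10, k = 4)
  anchors <- c(names(ds$pops)[match("I", ds$pops)],
               names(ds$pops)[match("J", ds$pops)])
  anchors <- setNames(ds$pops[anchors], anchors)
  assignment <- classify_subspecies(pca, anchors)
  keep <- filter_expressed(ds$counts)
  vst <- normalize_vst(ds$counts[keep, , drop = FALSE])
  expr <- int_rows(vst, seed = derive_seed(seed, 1L))

  ## divergence
  de <- de_scan(expr, ds$samples, assignment, fdr = fdr_divergence)
  enc <- encode_pav(ds$counts)
  pav <- pav_scan(enc$binary, ds$samples, assignment, genes = enc$candidates,
                  fdr = fdr_divergence)

  ## diversity (equal group sizes by seeded subsampling)
  acc_norm <- normalized_accession_counts(ds$counts[keep, , drop = FALSE],
                                          ds$samples)
  cv <- expression_cv(acc_norm, unclass(assignment))
  pi_sites <- group_pi(ds$genotypes, unclass(assignment), maf_min = 0.05,
                       equalize = TRUE, seed = derive_seed(seed, 2L))

  ## heritability across subspecies
  broad <- fit_broad_h2(expr, ds$samples)
  null <- rlrt_null(attr(broad, "ni"), B = B_rlrt, seed = derive_seed(seed, 3L))
  broad$p <- empirical_p(broad$rlrt, null)
  broad$q <- bh_adjust(broad$p)
  broad$significant <- broad$q <= fdr_h2
  grm <- build_grm(ds$genotypes)
  blup <- accession_blup(expr, ds$samples)
  y_acc <- int_rows(blup, seed = derive_seed(seed, 4L))
  narrow <- fit_narrow_h2(y_acc, grm, B_null = B_rlrt,
                          seed = derive_seed(seed, 9L))
  narrow$q <- bh_adjust(narrow$p)
  narrow$significant <- !is.na(narrow$q) & narrow$q <= fdr_h2

  ## within-subspecies heritability
  within <- within_subspecies_h2(ds$counts, ds$samples, ds$genotypes,
                                 assignment, seed = derive_seed(seed, 5L),
                                 B_null = B_rlrt, fdr = fdr_h2)

  ## heritability differences (J minus I), genes measured in both scopes
  common_b <- intersect(within$I$broad$gene_id, within$J$broad$gene_id)
  dH_obs <- setNames(
    within$J$broad$H2[match(common_b, within$J$broad$gene_id)] -
      within$I$broad$H2[match(common_b, within$I$broad$gene_id)], common_b)
  n_grp <- length(within$I$accessions)
  delta_broad <- delta_h_permutation(dH_obs, kind = "broad", expr = expr,
                                     samples = ds$samples,
                                     group_size = n_grp, B = B_delta,
                                     seed = derive_seed(seed, 6L))
  common_n <- intersect(within$I$narrow$gene_id, within$J$narrow$gene_id)
  dh_obs <- setNames(
    within$J$narrow$h2[match(common_n, within$J$narrow$gene_id)] -
      within$I$narrow$h2[match(common_n, within$I$narrow$gene_id)], common_n)
  if (!is.null(delta_genes) && length(dh_obs) > delta_genes)
    dh_obs <- dh_obs[seq_len(delta_genes)]
  delta_narrow <- delta_h_permutation(dh_obs, kind = "narrow", Y = y_acc,
                                      genotypes = ds$genotypes,
                                      group_size = n_grp, B = B_delta,
                                      seed = derive_seed(seed, 7L))

  ## joint cis-eQTL scan
  eqtl_genes <- rownames(y_acc)
  if (h2_filter) {
    sig <- union(within$I$broad$gene_id[within$I$broad$significant],
                 within$J$broad$gene_id[within$J$broad$significant])
    eqtl_genes <- intersect(eqtl_genes, sig)
  }
  eqtl <- NULL
  if (length(eqtl_genes)) {
    eqtl <- eqtl_scan(y_acc[eqtl_genes, , drop = FALSE], ds$genotypes,
                      ds$genes, assignment, covariates = pca$scores,
                      B = B_eqtl, fdr = fdr_eqtl,
                      seed = derive_seed(seed, 8L))
  }

  ## selection scan around classified eQTL
  selection <- NULL
  if (!is.null(eqtl) && any(eqtl$calls$call != "none")) {
    selection <- tryCatch(
      selection_scan(eqtl$calls, ds$genotypes, unclass(assignment),
                     chrom_lengths = config$chromosome_lengths),
      error = function(e) { warnf("selection scan skipped: %s", conditionMessage(e)); NULL })
  }

  res <- structure(list(dataset = ds, pca = pca, assignment = assignment,
                        expressed_genes = keep, expr = expr, de = de,
                        pav = pav, cv = cv, pi_sites = pi_sites,
                        broad = broad, narrow = narrow, within = within,
                        delta_broad = delta_broad, delta_narrow = delta_narrow,
                        eqtl = eqtl, selection = selection),
                   class = "oryzadiv_pipeline")

  if (!is.null(out_dir)) {
    tables <- list(de_results = de, pav_results = pav, cv = cv,
                   site_pi = pi_sites, h2_broad = broad, h2_narrow = narrow,
                   h2_broad_I = within$I$broad, h2_broad_J = within$J$broad,
                   h2_narrow_I = within$I$narrow, h2_narrow_J = within$J$narrow,
                   delta_h_broad = delta_broad, delta_h_narrow = delta_narrow)
    if (!is.null(eqtl)) tables$eqtl_calls <- eqtl$calls
    if (!is.null(selection)) {
      tables$selection_summary <- selection$summary
      tables$selection_windows <- selection$eqtl_windows
    }
    write_results(tables, out_dir, force = force)
  }
  res
}

#' @export
print.oryzadiv_pipeline <- function(x, ...) {
  cat("oryzadiv pipeline results\n")
  cat(sprintf("  expressed genes: %d of %d\n", length(x$expressed_genes),
              nrow(x$dataset$counts)))
  cat(sprintf("  DE genes (q <= 0.001): %d; PAV genes: %d\n",
              sum(x$de$significant), sum(x$pav$significant)))
  cvm <- tapply(x$cv$cv, x$cv$group, mean, na.rm = TRUE)
  pim <- tapply(x$pi_sites$pi, x$pi_sites$group, mean)
  cat(sprintf("  mean CV: %s; mean pi: %s\n",
              paste(sprintf("%s %.2f", names(cvm), cvm), collapse = ", "),
              paste(sprintf("%s %.3f", names(pim), pim), collapse = ", ")))
  cat(sprintf("  significant H2 genes: %d; significant h2 genes: %d\n",
              sum(x$broad$significant), sum(x$narrow$significant, na.rm = TRUE)))
  if (!is.null(x$eqtl)) print(x$eqtl)
  if (!is.null(x$selection)) print(x$selection)
  invisible(x)
}
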