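#' Write a simulated dataset to disk in standard formats
#'
#' Writes \code{genotypes.vcf} (VCF 4.2; inbred haploid dosages exported as
#' homozygous diploid GT), \code{counts.tsv}, \code{genes.tsv},
#' \code{samples.tsv} and \code{truth.tsv}.
#'
#' @param ds a \code{rice_dataset} from \code{\link{simulate_dataset}}.
#' @param out_dir output directory (created if absent).
#' @param force overwrite existing files.
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(ds, out_dir, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("genotypes.vcf", "counts.tsv", "genes.tsv",
                                "samples.tsv", "truth.tsv"))
  if (!force && any(file.exists(paths)))
    stopf("output files exist in %s; use force = TRUE", out_dir)
  write_vcf(ds$genotypes, paths[1],
            contigs = ds$config$chromosome_lengths)
  cnt <- data.frame(gene_id = rownames(ds$counts), ds$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cnt, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$genes, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  samp <- ds$samples
  samp$subpopulation <- samp$subspecies
  utils::write.table(samp, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth, paths[5], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Plain-text VCF 4.2 export of haploid dosages as homozygous diploid GT.
write_vcf <- function(gt, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=oryzadiv", con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  acc <- rownames(gt$dosage)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", acc), collapse = "\t"), con)
  gtchar <- matrix("./.", ncol(gt$dosage), nrow(gt$dosage))  # SNPs x accessions
  d <- t(gt$dosage)
  gtchar[!is.na(d) & d == 0] <- "0/0"
  gtchar[!is.na(d) & d == 1] <- "1/1"
  body <- paste(gt$snps$chrom, gt$snps$pos, gt$snps$snp_id, gt$snps$ref,
                gt$snps$alt, ".", "PASS", ".", "GT",
                apply(gtchar, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Load and cross-validate a dataset bundle
#'
#' Reads genotypes (VCF), counts, gene annotation and sample metadata, and
#' validates the cross-references.  Diploid genotypes are collapsed to
#' haploid dosages (0/0 -> 0, 1/1 -> 1, ./. -> missing); heterozygous calls
#' become missing with a counted warning (the panel is inbred, so hets are
#' treated as genotyping errors); multi-allelic records are skipped with a
#' count.  Samples present in the count matrix but absent from the metadata
#' are an error.
#'
#' @param vcf_path,counts_path,genes_path,samples_path file paths.
#' @return a \code{rice_dataset} (without simulation truth).
#' @export
load_dataset <- function(vcf_path, counts_path, genes_path, samples_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    warnf("%d multi-allelic record(s) skipped", sum(multi))
  gtm <- vcfR::extract.gt(v, element = "GT")
  gtm <- gtm[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  g <- gsub("|", "/", gtm, fixed = TRUE)
  dos <- matrix(NA_real_, nrow(g), ncol(g))
  dos[g == "0/0" | g == "0"] <- 0
  dos[g == "1/1" | g == "1"] <- 1
  het <- g %in% c("0/1", "1/0")
  n_het <- sum(het)
  if (n_het > 0)
    warnf("%d heterozygous call(s) set to missing (inbred panel)", n_het)
  dosage <- t(dos)                              # accessions x SNPs
  rownames(dosage) <- colnames(gtm)
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste(fix$CHROM, fix$POS, sep = "_"), fix$ID)
  colnames(dosage) <- snp_id
  snps <- data.frame(snp_id = snp_id, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  gt <- genotype_table(dosage, snps)

  cnt <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(cnt$gene_id)) stopf("duplicated gene ids in %s", counts_path)
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(counts) <- cnt$gene_id
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stopf("negative counts in %s", counts_path)

  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) stopf("duplicated gene ids in %s", genes_path)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  unmapped <- setdiff(colnames(counts), samples$sample_id)
  if (length(unmapped))
    stopf("sample(s) in counts but not in metadata: %s",
          paste(unmapped, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  pops <- NULL
  if ("subspecies" %in% names(samples)) {
    pops <- tapply(samples$subspecies, samples$accession_id, function(z) z[1])
    pops <- setNames(as.character(pops), names(pops))
  }
  structure(list(genotypes = gt, counts = counts, genes = genes,
                 samples = samples, pops = pops, truth = NULL, config = NULL),
            class = "rice_dataset")
}

#' Write result tables as TSV
#'
#' One TSV per named table, with a header row, floats at 6 significant
#' digits and \code{NA} for undefined values.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory.
#' @param force overwrite existing files.
#' @return invisibly, the files written.
#' @export
write_results <- function(tables, out_dir, force = FALSE) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, paste0(names(tables), ".tsv"))
  if (!force && any(file.exists(paths)))
    stopf("result files exist in %s; use force = TRUE", out_dir)
  for (i in seq_along(tables)) {
    tab <- as.data.frame(tables[[i]])
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 6)
    utils::write.table(tab, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(paths)
}
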