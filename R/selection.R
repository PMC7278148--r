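#' Nucleotide diversity in windows around classified eQTL
#'
#' For each called eQTL (top SNP) and each group, the mean site-pi over
#' SNPs within \code{radius} bp of the eQTL SNP.
#'
#' @param calls the \code{calls} table of an \code{\link{eqtl_scan}}
#'   (rows with \code{call == "none"} are ignored).
#' @param gt a \code{\link{genotype_table}}.
#' @param groups named accession -> group vector (the two subspecies).
#' @param radius window half-width around the eQTL SNP (default 100000).
#' @param maf_min within-group MAF filter for the site-pi set (default 0:
#'   all segregating sites contribute).
#' @return data.frame: gene_id, call, group, chrom, pos, mean_pi, n_sites.
#' @export
eqtl_window_pi <- function(calls, gt, groups, radius = 100000, maf_min = 0) {
  hits <- calls[calls$call != "none", , drop = FALSE]
  if (!nrow(hits)) stopf("no classified eQTL to scan")
  sites <- group_pi(gt, groups, maf_min = maf_min)
  out <- lapply(unique(sites$group), function(g) {
    s <- sites[sites$group == g, , drop = FALSE]
    mp <- numeric(nrow(hits)); ns <- integer(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      sel <- s$chrom == hits$top_chrom[i] &
        abs(s$pos - hits$top_pos[i]) <= radius
      ns[i] <- sum(sel)
      mp[i] <- if (ns[i]) mean(s$pi[sel]) else NA_real_
    }
    data.frame(gene_id = hits$gene_id, call = hits$call, group = g,
               chrom = hits$top_chrom, pos = hits$top_pos,
               mean_pi = mp, n_sites = ns, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(is.na(res$mean_pi)))
    warnf("%d empty eQTL window(s)", sum(is.na(res$mean_pi)))
  res
}

#' Genome-wide background window diversity
#'
#' Tiles the genome into consecutive windows (1-based closed intervals),
#' removes SNPs within \code{radius} of any called eQTL, removes
#' low-diversity sites (within-group MAF < \code{low_div_maf} in at least
#' \code{low_div_groups} of the groups), and averages site-pi per window
#' and group.
#'
#' @inheritParams eqtl_window_pi
#' @param window background tile width in bp (default 100000).
#' @param low_div_maf,low_div_groups the parameterized exclusion rule.
#' @param chrom_lengths optional named chromosome lengths; inferred from
#'   the largest SNP position per chromosome when missing.
#' @return data.frame: chrom, start, end, group, mean_pi, n_sites,
#'   label = "background".
#' @export
background_window_pi <- function(gt, groups, calls, window = 100000,
                                 radius = 100000, low_div_maf = 0.1,
                                 low_div_groups = 2, maf_min = 0,
                                 chrom_lengths = NULL) {
  hits <- calls[calls$call != "none", , drop = FALSE]
  snps <- gt$snps
  near <- rep(FALSE, nrow(snps))
  for (i in seq_len(nrow(hits))) {
    near <- near | (snps$chrom == hits$top_chrom[i] &
                      abs(snps$pos - hits$top_pos[i]) <= radius)
  }
  gmaf <- snp_maf(gt, groups)
  lowdiv <- colSums(gmaf < low_div_maf, na.rm = TRUE) >= low_div_groups
  keep <- which(!near & !lowdiv)
  if (!length(keep)) stopf("no background SNPs survive the exclusion rules")
  bg <- subset_genotypes(gt, snp_idx = keep)
  sites <- group_pi(bg, groups, maf_min = maf_min)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(snps$pos, snps$chrom, max)
  }
  wins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1L, chrom_lengths[[ch]], by = window)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window - 1, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  }))
  out <- window_mean_pi(sites, wins)
  out <- out[!is.na(out$mean_pi), , drop = FALSE]
  if (!nrow(out)) stopf("no surviving background windows")
  out$label <- "background"
  rownames(out) <- NULL
  out
}

#' Compare eQTL-window diversity to the genome-wide background
#'
#' Per (eQTL class, group): Welch two-sided t-test of eQTL-window mean pi
#' against background-window mean pi, with the percent difference of means.
#' Each eQTL window is flagged low-diversity when its mean pi is at or
#' below the group's empirical background \code{quantile}.
#'
#' @param eqtl_windows output of \code{\link{eqtl_window_pi}}.
#' @param background output of \code{\link{background_window_pi}}.
#' @param quantile background quantile for the low-diversity flag.
#' @return object of class \code{selection_scan}: list with \code{summary}
#'   (per class x group: means, t, p, percent difference, flag rate) and
#'   \code{eqtl_windows} (input with \code{low_diversity} flags appended).
#' @export
compare_and_flag <- function(eqtl_windows, background, quantile = 0.05) {
  groups <- unique(background$group)
  thr <- vapply(groups, function(g)
    stats::quantile(background$mean_pi[background$group == g], quantile,
                    na.rm = TRUE, names = FALSE), numeric(1))
  names(thr) <- groups
  ew <- eqtl_windows
  ew$low_diversity <- !is.na(ew$mean_pi) & ew$mean_pi <= thr[ew$group]
  rows <- list()
  for (cl in unique(ew$call)) for (g in groups) {
    x <- ew$mean_pi[ew$call == cl & ew$group == g]
    x <- x[!is.na(x)]
    y <- background$mean_pi[background$group == g]
    y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 10) {
      warnf("comparison skipped for class %s in group %s (too few windows)", cl, g)
      next
    }
    tt <- t.test(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, group = g, n_eqtl = length(x), n_background = length(y),
      mean_pi_eqtl = mean(x), mean_pi_background = mean(y),
      t = unname(tt$statistic), p = tt$p.value,
      percent_difference = 100 * (mean(x) - mean(y)) / mean(y),
      flag_rate = mean(ew$low_diversity[ew$call == cl & ew$group == g],
                       na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, rows), eqtl_windows = ew,
                 thresholds = thr, quantile = quantile),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat("selection_scan: eQTL-window vs background nucleotide diversity\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-17s in %s: pi %.4f vs %.4f (%+.1f%%), p = %.3g, flags %.1f%%\n",
                s$class[i], s$group[i], s$mean_pi_eqtl[i],
                s$mean_pi_background[i], s$percent_difference[i], s$p[i],
                100 * s$flag_rate[i]))
  invisible(x)
}

#' One-call selection scan around classified eQTL
#'
#' @inheritParams eqtl_window_pi
#' @inheritParams background_window_pi
#' @inheritParams compare_and_flag
#' @return a \code{selection_scan} object.
#' @export
selection_scan <- function(calls, gt, groups, radius = 100000,
                           window = 100000, low_div_maf = 0.1,
                           low_div_groups = 2, quantile = 0.05,
                           chrom_lengths = NULL) {
  ew <- eqtl_window_pi(calls, gt, groups, radius = radius)
  bg <- background_window_pi(gt, groups, calls, window = window,
                             radius = radius, low_div_maf = low_div_maf,
                             low_div_groups = low_div_groups,
                             chrom_lengths = chrom_lengths)
  compare_and_flag(ew, bg, quantile = quantile)
}
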