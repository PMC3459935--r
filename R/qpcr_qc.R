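#' Quality-filter genes in a Ct set
#'
#' Removes genes whose endogenous (non-calibrator, non-water) wells are
#' predominantly above the high-Ct threshold or at the absent sentinel 999
#' (majority rule: more than \code{absent_fraction} of wells), and genes
#' whose calibrator replicates across plates contain more than
#' \code{calibrator_outlier_fraction} outliers, an outlier being a well
#' beyond median +/- 3 MAD of the gene's calibrator Ct values.
#'
#' @param ct a Ct set (long data.frame, see [generate_ct_plates()]).
#' @param high_ct_threshold Ct above which a well counts as too high.
#' @param absent_fraction fraction of bad wells beyond which a gene is
#'   dropped.
#' @param calibrator_outlier_fraction calibrator outlier fraction beyond
#'   which a gene is dropped.
#' @param min_calibrator_replicates minimum number of calibrator replicates
#'   (plates) for the outlier rule to be applied; the median/MAD spread
#'   estimate is too unstable below this.
#' @return list with \code{ct} (filtered set) and \code{report}
#'   (data.frame \code{gene}, \code{reason}, \code{detail}).
#' @export
qc_filter_genes <- function(ct, high_ct_threshold = 30,
                            absent_fraction = 0.5,
                            calibrator_outlier_fraction = 0.20,
                            min_calibrator_replicates = 8) {
  endo <- ct[!ct$is_calibrator & !ct$is_water, ]
  cal <- ct[ct$is_calibrator, ]
  if (!nrow(cal)) stop("no calibrator wells: cannot assess outliers")
  report <- data.frame(gene = character(), reason = character(),
                       detail = character(), stringsAsFactors = FALSE)
  for (g in unique(ct$gene)) {
    cts <- endo$ct[endo$gene == g]
    bad <- mean(cts == 999 | cts > high_ct_threshold)
    if (length(cts) && bad > absent_fraction) {
      report <- rbind(report, data.frame(
        gene = g, reason = "absent",
        detail = sprintf("%.0f%% of wells >%g or absent", 100 * bad,
                         high_ct_threshold)))
      next
    }
    cc <- cal$ct[cal$gene == g & cal$ct != 999]
    if (length(cc) >= min_calibrator_replicates) {
      med <- stats::median(cc)
      madv <- stats::mad(cc)
      out_frac <- mean(abs(cc - med) > 3 * madv)
      if (out_frac > calibrator_outlier_fraction) {
        report <- rbind(report, data.frame(
          gene = g, reason = "calibrator_outliers",
          detail = sprintf("%.0f%% calibrator outliers", 100 * out_frac)))
      }
    }
  }
  keep <- setdiff(unique(ct$gene), report$gene)
  if (!length(keep)) {
    stop("all genes removed by QC; check thresholds and input: ",
         paste(report$reason, collapse = ", "))
  }
  list(ct = ct[ct$gene %in% keep, ], report = report)
}
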