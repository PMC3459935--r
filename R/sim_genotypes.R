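#' Generate gene annotation for the simulated panel
#'
#' Places each gene's coding sequence on a chromosome with a strand and a
#' 1-based inclusive coordinate span, spaced far enough apart that cis
#' windows never overlap between genes.
#'
#' @param genes character vector of gene ids.
#' @param seed integer seed.
#' @return data.frame with columns \code{gene}, \code{chrom}, \code{strand},
#'   \code{cds_start}, \code{cds_end}.
#' @export
make_gene_annotation <- function(genes, seed = 1) {
  set.seed(seed)
  n <- length(genes)
  chrom <- paste0("chr", rep_len(1:22, n))
  start <- 1e6 + (seq_len(n) - 1L) %/% 22L * 1e6
  len <- round(stats::runif(n, 1e3, 1e4))
  data.frame(gene = genes, chrom = chrom,
             strand = sample(c("+", "-"), n, replace = TRUE),
             cds_start = start, cds_end = start + len,
             stringsAsFactors = FALSE)
}

#' SNP simulation configuration
#'
#' @param n_per_gene SNPs placed in or near each gene.
#' @param maf_range minor-allele frequency range, within (0, 0.5].
#' @param frac_hwe_violators fraction of SNPs drawn out of Hardy-Weinberg
#'   equilibrium (heterozygote deficit, inbreeding-style mixture).
#' @param frac_low_call fraction of SNPs given a low call rate.
#' @param low_call_missing missing fraction for low-call SNPs (> 0.05).
#' @return list of class \code{snp_config}.
#' @export
snp_config <- function(n_per_gene = 3, maf_range = c(0.1, 0.5),
                       frac_hwe_violators = 0.05, frac_low_call = 0.05,
                       low_call_missing = 0.10) {
  stopifnot(low_call_missing > 0.05)
  structure(list(n_per_gene = n_per_gene, maf_range = maf_range,
                 frac_hwe_violators = frac_hwe_violators,
                 frac_low_call = frac_low_call,
                 low_call_missing = low_call_missing),
            class = "snp_config")
}

#' Generate biallelic cis SNP genotypes for a cohort
#'
#' Draws minor-allele dose matrices (0/1/2, coded by minor-allele count).
#' SNPs in Hardy-Weinberg equilibrium are binomial(2, MAF); designated
#' violators come from an inbreeding mixture with a heterozygote deficit;
#' designated low-call SNPs receive more than 5\% missing entries. For genes
#' whose truth carries a nonzero cis-eQTL effect, the first SNP of the gene
#' is placed inside the CDS and its per-allele effect is added to the gene's
#' expression at every visit (when \code{expr} is supplied).
#'
#' @param truth a \code{sim_truth} (source of \code{eqtl_beta}).
#' @param cohort a cohort table (source of subject ids).
#' @param config a [snp_config()].
#' @param seed integer seed.
#' @param genes gene annotation from [make_gene_annotation()]; generated
#'   from the truth's genes by default.
#' @param expr optional \code{expr_set}; returned with eQTL effects added.
#' @return list with \code{doses} (SNP x subject integer matrix with NAs),
#'   \code{snps} (annotation: \code{snp}, \code{chrom}, \code{pos},
#'   \code{gene}, \code{maf}, \code{is_violator}, \code{is_low_call},
#'   \code{is_eqtl}), \code{genes} (the gene annotation), and \code{expr}
#'   (modified copy, or NULL).
#' @export
generate_genotypes <- function(truth, cohort, config = snp_config(),
                               seed = 1, genes = NULL, expr = NULL) {
  stopifnot(inherits(config, "snp_config"))
  if (any(config$maf_range <= 0) || any(config$maf_range > 0.5)) {
    stop("MAF must lie in (0, 0.5]")
  }
  set.seed(seed)
  if (is.null(genes)) genes <- make_gene_annotation(truth$genes, seed = seed)
  subjects <- unique(cohort$subject_id)
  n <- length(subjects)

  snp_rows <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    is_eqtl_gene <- truth$eqtl_beta[g$gene] != 0
    for (k in seq_len(config$n_per_gene)) {
      if (k == 1) {
        # inside the CDS (always cis); carries the eQTL effect if any
        pos <- round(stats::runif(1, g$cds_start, g$cds_end))
      } else if (k == 2) {
        # in the flank, still within a 10 kb window either side
        pos <- g$cds_start - round(stats::runif(1, 1, 9000))
      } else {
        # far outside any cis window
        pos <- g$cds_end + 5e4 + round(stats::runif(1, 0, 1e4))
      }
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        snp = sprintf("rs_%s_%d", g$gene, k), chrom = g$chrom, pos = pos,
        gene = g$gene,
        maf = stats::runif(1, config$maf_range[1], config$maf_range[2]),
        is_eqtl = (k == 1) && is_eqtl_gene, stringsAsFactors = FALSE)
    }
  }
  snps <- do.call(rbind, snp_rows)
  m <- nrow(snps)
  snps$is_violator <- stats::runif(m) < config$frac_hwe_violators
  snps$is_low_call <- stats::runif(m) < config$frac_low_call
  # eQTL SNPs stay clean so their associations are testable
  snps$is_violator[snps$is_eqtl] <- FALSE
  snps$is_low_call[snps$is_eqtl] <- FALSE

  doses <- matrix(NA_integer_, m, n, dimnames = list(snps$snp, subjects))
  f_inb <- 0.6  # inbreeding coefficient of the disequilibrium mixture
  for (i in seq_len(m)) {
    q <- snps$maf[i]
    if (snps$is_violator[i]) {
      pr <- c((1 - q)^2 + f_inb * q * (1 - q),
              2 * q * (1 - q) * (1 - f_inb),
              q^2 + f_inb * q * (1 - q))
      doses[i, ] <- sample(0:2, n, replace = TRUE, prob = pr)
    } else {
      doses[i, ] <- stats::rbinom(n, 2, q)
    }
    if (snps$is_low_call[i]) {
      doses[i, stats::runif(n) < config$low_call_missing] <- NA_integer_
    }
  }

  if (!is.null(expr)) {
    for (i in which(snps$is_eqtl)) {
      g <- snps$gene[i]
      beta <- truth$eqtl_beta[g]
      d <- doses[i, expr$samples$subject_id]
      d[is.na(d)] <- 0L
      expr$mat[g, ] <- expr$mat[g, ] + beta * d
    }
  }
  list(doses = doses, snps = snps, genes = genes, expr = expr)
}
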