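#' Map SNPs to genes through strand-aware cis windows
#'
#' A SNP is cis to a gene when it lies on the same chromosome within a
#' closed window around the coding sequence extended \code{upstream} bases
#' upstream and \code{downstream} bases downstream of transcription: for a
#' plus-strand gene \code{[cds_start - upstream, cds_end + downstream]},
#' mirrored for minus-strand genes. Coordinates are 1-based inclusive.
#'
#' @param snps data.frame with \code{snp}, \code{chrom}, \code{pos}.
#' @param genes data.frame with \code{gene}, \code{chrom}, \code{strand}
#'   (\code{"+"}/\code{"-"}), \code{cds_start}, \code{cds_end}.
#' @param upstream,downstream window extents in bases (defaults 10 kb
#'   upstream, 15 kb downstream).
#' @return data.frame of \code{snp}, \code{gene} pairs.
#' @export
map_cis_pairs <- function(snps, genes, upstream = 10000,
                          downstream = 15000) {
  stopifnot(all(genes$cds_start <= genes$cds_end))
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("unknown strand for gene(s): ",
         paste(genes$gene[!genes$strand %in% c("+", "-")], collapse = ", "))
  }
  lo <- ifelse(genes$strand == "+", genes$cds_start - upstream,
               genes$cds_start - downstream)
  hi <- ifelse(genes$strand == "+", genes$cds_end + downstream,
               genes$cds_end + upstream)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    hit <- snps$chrom == genes$chrom[i] & snps$pos >= lo[i] &
      snps$pos <= hi[i]
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        snp = snps$snp[hit], gene = genes$gene[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(snp = character(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Hardy-Weinberg equilibrium test
#'
#' Chi-square goodness of fit (1 df) of the observed genotype counts
#' against the frequencies implied by the estimated allele frequency, with
#' an exact enumeration backend for small samples. Monomorphic SNPs have
#' no defined test and come back flagged with \code{p = NA}.
#'
#' @param counts integer vector \code{(n_AA, n_Aa, n_aa)} (major
#'   homozygote, heterozygote, minor homozygote).
#' @param method \code{"chisq"} (default) or \code{"exact"}.
#' @return list \code{statistic} (chi-square, NA for exact), \code{p},
#'   \code{method}, \code{flagged} (TRUE when monomorphic).
#' @export
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(length(counts) == 3, all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  q <- (2 * counts[3] + counts[2]) / (2 * n)  # minor-allele frequency
  if (q == 0 || q == 1) {
    return(list(statistic = NA_real_, p = NA_real_, method = method,
                flagged = TRUE))
  }
  if (method == "chisq") {
    expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    stat <- sum((counts - expd)^2 / expd)
    list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
         method = method, flagged = FALSE)
  } else {
    # exact test: enumerate heterozygote counts at fixed allele counts
    n_minor <- 2 * counts[3] + counts[2]
    het_obs <- counts[2]
    hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
    logp <- vapply(hets, function(h) {
      hom_min <- (n_minor - h) / 2
      hom_maj <- n - h - hom_min
      lgamma(n + 1) - lgamma(hom_maj + 1) - lgamma(h + 1) -
        lgamma(hom_min + 1) + h * log(2) +
        lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
        lgamma(2 * n + 1)
    }, 0)
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    p <- sum(pr[pr <= pr[match(het_obs, hets)] + 1e-12])
    list(statistic = NA_real_, p = min(1, p), method = method,
         flagged = FALSE)
  }
}

#' Genotype quality control
#'
#' Retains SNPs with call rate at least \code{call_rate_min} (inclusive)
#' and Hardy-Weinberg p-value strictly above \code{hwe_alpha}; monomorphic
#' SNPs (no defined HWE test) are removed with their own reason.
#'
#' @param geno list with \code{doses} (SNP x subject matrix) and
#'   \code{snps} annotation, as from [generate_genotypes()].
#' @param call_rate_min minimum non-missing fraction.
#' @param hwe_alpha HWE significance threshold.
#' @param hwe_method backend for [hwe_test()].
#' @return list with filtered \code{geno} and a \code{report} data.frame
#'   (\code{snp}, \code{call_rate}, \code{hwe_p}, \code{kept},
#'   \code{reason}).
#' @export
genotype_qc <- function(geno, call_rate_min = 0.95, hwe_alpha = 0.05,
                        hwe_method = "chisq") {
  d <- geno$doses
  cr <- rowMeans(!is.na(d))
  hwe_p <- apply(d, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    hwe_test(c(sum(v == 0), sum(v == 1), sum(v == 2)),
             method = hwe_method)$p
  })
  reason <- rep("", nrow(d))
  reason[cr < call_rate_min] <- "low_call_rate"
  reason[reason == "" & is.na(hwe_p)] <- "monomorphic"
  reason[reason == "" & hwe_p <= hwe_alpha] <- "hwe_failure"
  kept <- reason == ""
  report <- data.frame(snp = rownames(d), call_rate = cr, hwe_p = hwe_p,
                       kept = kept, reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  geno$doses <- d[kept, , drop = FALSE]
  geno$snps <- geno$snps[match(rownames(geno$doses), geno$snps$snp), ]
  list(geno = geno, report = report)
}

#' Single SNP-gene allele-dose association
#'
#' Linear mixed model of log2 expression on minor-allele dose (log-additive
#' coding 0/1/2) with optional fixed covariates and a centre random
#' intercept; missing doses are dropped pairwise. SNPs monomorphic in the
#' analysis subset are skipped with a flag.
#'
#' @param y log2 expression per subject (named by subject id).
#' @param dose minor-allele dose per subject (same order).
#' @param covar data.frame of per-subject covariates (e.g. \code{sex},
#'   \code{bmi}), or NULL.
#' @param centre centre id per subject (random intercept), or NULL for
#'   plain least squares.
#' @return list \code{beta}, \code{se}, \code{p}, \code{n},
#'   \code{skipped}.
#' @export
fit_eqtl <- function(y, dose, covar = NULL, centre = NULL) {
  ok <- !is.na(y) & !is.na(dose)
  if (!is.null(covar)) ok <- ok & stats::complete.cases(covar)
  y <- y[ok]
  dose <- dose[ok]
  if (length(unique(dose)) < 2) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n = length(y), skipped = TRUE))
  }
  fr <- data.frame(y = y, dose = dose)
  if (!is.null(covar)) fr <- cbind(fr, covar[ok, , drop = FALSE])
  rhs <- paste(setdiff(colnames(fr), "y"), collapse = " + ")
  if (!is.null(centre)) {
    fr$centre <- factor(centre[ok])
    fm <- suppressMessages(lme4::lmer(
      stats::as.formula(paste("y ~", rhs, "+ (1 | centre)")),
      data = fr, REML = TRUE,
      control = screen_lmer_control()))
    b <- lme4::fixef(fm)
    v <- as.matrix(stats::vcov(fm))
  } else {
    fm <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = fr)
    b <- stats::coef(fm)
    v <- stats::vcov(fm)
  }
  est <- unname(b["dose"])
  se <- sqrt(v["dose", "dose"])
  df <- nrow(fr) - length(b)
  list(beta = est, se = se, p = 2 * stats::pt(-abs(est / se), df),
       n = nrow(fr), skipped = FALSE)
}

#' cis-eQTL screen over SNP-gene pairs at one visit
#'
#' @param expr an \code{expr_set} restricted to one visit (see
#'   [expr_at_cid()]).
#' @param geno genotype list (\code{doses}, \code{snps}).
#' @param pairs data.frame \code{snp}, \code{gene} from
#'   [map_cis_pairs()].
#' @param pheno phenotype table (for covariates and centre).
#' @param covariates fixed covariates taken from the baseline phenotype
#'   rows.
#' @param cid visit of the expression data (for covariate lookup).
#' @return data.frame \code{snp}, \code{gene}, \code{beta}, \code{se},
#'   \code{p}, \code{q}, \code{n}, \code{skipped}.
#' @export
eqtl_screen <- function(expr, geno, pairs, pheno,
                        covariates = c("sex"), cid = 1) {
  subj <- expr$samples$subject_id
  ph <- pheno[pheno$cid == cid, ]
  ph <- ph[match(subj, ph$subject_id), ]
  covar <- if (length(covariates)) {
    d <- ph[, covariates, drop = FALSE]
    for (v in colnames(d)) if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
    d
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sn <- pairs$snp[i]
    g <- pairs$gene[i]
    if (!sn %in% rownames(geno$doses) || !g %in% rownames(expr$mat)) {
      return(NULL)
    }
    r <- fit_eqtl(expr$mat[g, ], geno$doses[sn, subj], covar, ph$centre)
    data.frame(snp = sn, gene = g, beta = r$beta, se = r$se, p = r$p,
               n = r$n, skipped = r$skipped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(snp = character(), gene = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      q = numeric(), n = integer(), skipped = logical()))
  }
  out$q <- bh_adjust(out$p)$q
  out[, c("snp", "gene", "beta", "se", "p", "q", "n", "skipped")]
}

#' Persistent cis associations across the dietary intervention
#'
#' Keeps the SNP-gene pairs BH-significant at baseline whose tests at the
#' two later visits are BH-significant as well.
#'
#' @param res_cid1,res_cid2,res_cid3 [eqtl_screen()] results on the same
#'   pairs.
#' @param alpha FDR level.
#' @return data.frame of persistent \code{snp}, \code{gene} pairs.
#' @export
eqtl_persistence <- function(res_cid1, res_cid2, res_cid3, alpha = 0.05) {
  key <- function(d) paste(d$snp, d$gene, sep = "|")
  sig <- function(d) key(d)[!is.na(d$q) & d$q <= alpha]
  keep <- intersect(sig(res_cid1), intersect(sig(res_cid2), sig(res_cid3)))
  d <- res_cid1[key(res_cid1) %in% keep, c("snp", "gene")]
  rownames(d) <- NULL
  d
}

#' Association of genotype with diet-induced expression change
#'
#' Same model contract as [fit_eqtl()] but on a within-subject log2
#' expression ratio (e.g. CID2/CID1): a purely level-acting cis variant
#' shows no association with the change score.
#'
#' @param expr an \code{expr_set} covering both visits.
#' @param geno genotype list.
#' @param pairs SNP-gene pairs.
#' @param pheno phenotype table.
#' @param from,to the two visits forming \code{log2(to / from)}.
#' @param covariates fixed covariates (taken at \code{from}).
#' @return data.frame as [eqtl_screen()].
#' @export
delta_association <- function(expr, geno, pairs, pheno, from = 1, to = 2,
                              covariates = c("sex")) {
  ea <- expr_at_cid(expr, from)
  eb <- expr_at_cid(expr, to)
  subj <- intersect(ea$samples$subject_id, eb$samples$subject_id)
  dmat <- eb$mat[, sample_key(subj, to), drop = FALSE] -
    ea$mat[, sample_key(subj, from), drop = FALSE]
  colnames(dmat) <- sample_key(subj, 1)
  dexpr <- expr_set(dmat,
                    data.frame(column_id = sample_key(subj, 1),
                               subject_id = subj, cid = 1L,
                               stringsAsFactors = FALSE),
                    method = sprintf("log2_ratio_cid%d_cid%d", to, from))
  eqtl_screen(dexpr, geno, pairs, pheno, covariates = covariates, cid = from)
}

#' Independence of genotype distribution and sex
#'
#' Chi-square test on the 2 x 3 sex-by-genotype table, switching to
#' Fisher's exact test when any expected cell count falls below 5.
#'
#' @param tab 2 x 3 matrix of counts (rows: sexes; columns: dose 0/1/2).
#' @return list \code{p}, \code{method}, \code{statistic} (NA for the
#'   exact test).
#' @export
sex_genotype_independence <- function(tab) {
  stopifnot(is.matrix(tab), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero-margin table")
  }
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd < 5)) {
    ft <- stats::fisher.test(tab)
    list(p = ft$p.value, method = "fisher", statistic = NA_real_)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(p = ct$p.value, method = "chisq",
         statistic = unname(ct$statistic))
  }
}
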