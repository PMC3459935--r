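# Readers and writers for the pipeline's plain-text interchange formats:
# long Ct TSV, cohort TSV, expression TSV, genotype dose TSV, minimal VCF
# (GT only), BED-like gene annotation TSV, truth JSON.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a long-format Ct TSV
#'
#' Columns: plate, set, well, sample_id, cid, gene, ct, is_calibrator,
#' is_water; absent Ct uses the sentinel 999.
#'
#' @param ct Ct set data.frame.
#' @param path file path.
#' @return the path (write) or the Ct set (read).
#' @export
write_ct_tsv <- function(ct, path) write_tsv(ct, path)

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  d <- read_tsv(path)
  d$is_calibrator <- as.logical(d$is_calibrator)
  d$is_water <- as.logical(d$is_water)
  d
}

#' Write / read a cohort TSV
#' @param cohort cohort table.
#' @param path file path.
#' @return the path (write) or the table (read).
#' @export
write_cohort_tsv <- function(cohort, path) write_tsv(cohort, path)

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) read_tsv(path)

#' Write / read an expression set as genes x samples TSV
#' @param expr an \code{expr_set}.
#' @param path file path.
#' @return the path (write) or an \code{expr_set} (read).
#' @export
write_expression_tsv <- function(expr, path) {
  d <- data.frame(gene = rownames(expr$mat), expr$mat, check.names = FALSE)
  write_tsv(d, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  cid <- suppressWarnings(as.integer(sub("^.*_", "", colnames(m))))
  expr_set(m, data.frame(column_id = colnames(m),
                         subject_id = sub("_[0-9]+$", "", colnames(m)),
                         cid = cid, stringsAsFactors = FALSE),
           method = "file")
}

#' Write / read a genotype dose TSV (SNPs x subjects)
#' @param geno genotype list (\code{doses}, \code{snps}).
#' @param path file path.
#' @return the path (write) or a genotype list (read; annotation columns
#'   \code{chrom}, \code{pos} are carried in the file).
#' @export
write_dose_tsv <- function(geno, path) {
  d <- data.frame(snp = rownames(geno$doses),
                  chrom = geno$snps$chrom[match(rownames(geno$doses),
                                                geno$snps$snp)],
                  pos = geno$snps$pos[match(rownames(geno$doses),
                                            geno$snps$snp)],
                  geno$doses, check.names = FALSE)
  write_tsv(d, path)
}

#' @rdname write_dose_tsv
#' @export
read_dose_tsv <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -(1:3), drop = FALSE])
  rownames(m) <- d$snp
  list(doses = m,
       snps = data.frame(snp = d$snp, chrom = d$chrom, pos = d$pos,
                         stringsAsFactors = FALSE))
}

#' Write a minimal VCF (GT field only) of the dose matrix
#'
#' Doses are encoded as genotypes 0/0, 0/1, 1/1 with ALT as the minor
#' allele; missing doses become "./.". The file uses placeholder REF/ALT
#' bases and is meant for interchange of genotype dose information, not
#' sequence content.
#'
#' @param geno genotype list (\code{doses}, \code{snps}).
#' @param path output path (uncompressed .vcf).
#' @return the path, invisibly.
#' @export
write_vcf_minimal <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       colnames(geno$doses)), collapse = "\t")), con)
  ann <- geno$snps[match(rownames(geno$doses), geno$snps$snp), ]
  gt_of <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(geno$doses))) {
    gts <- ifelse(is.na(geno$doses[i, ]), "./.",
                  gt_of[geno$doses[i, ] + 1L])
    writeLines(paste(c(sub("^chr", "", ann$chrom[i]), ann$pos[i],
                       ann$snp[i], "A", "G", ".", "PASS", ".", "GT", gts),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read the BED-like gene annotation TSV
#'
#' Columns gene, chrom, strand, cds_start, cds_end with 1-based inclusive
#' coordinates.
#'
#' @param genes gene annotation data.frame.
#' @param path file path.
#' @return the path (write) or the annotation (read).
#' @export
write_gene_tsv <- function(genes, path) write_tsv(genes, path)

#' @rdname write_gene_tsv
#' @export
read_gene_tsv <- function(path) read_tsv(path)

#' Serialize / restore simulation truth as JSON
#' @param truth a \code{sim_truth}.
#' @param path file path.
#' @return the path (write) or a \code{sim_truth} (read).
#' @export
write_truth_json <- function(truth, path) {
  x <- truth
  x$precision <- lapply(x$precision, unclass)
  x$config <- unclass(x$config)
  jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$precision <- lapply(x$precision, function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(x$genes, x$genes)
    m
  })
  for (v in c("gene_mean", "sex_effect", "bmi_slope", "diet_pattern",
              "diet_shift",
              "mets_shift", "eqtl_beta")) {
    x[[v]] <- stats::setNames(x[[v]], x$genes)
  }
  x$shared_edges <- as.matrix(x$shared_edges)
  class(x$config) <- "sim_config"
  class(x) <- "sim_truth"
  x
}
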