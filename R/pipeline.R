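#' Pipeline configuration
#'
#' Assembles the per-stage parameters of the full analysis: simulate a
#' cohort, normalize Ct plates, screen expression against the design
#' factors, infer the two sex networks, and run the cis-eQTL scan.
#'
#' @param seed global seed; each stage derives its own sub-seed
#'   deterministically.
#' @param n_subjects cohort size.
#' @param sim a [sim_config()] for the generative truth.
#' @param snp a [snp_config()] for the genotypes.
#' @param reference_gene reference gene id added to the panel for delta-Ct
#'   normalization.
#' @param normalize_method \code{"dct"}, \code{"quantile"} or
#'   \code{"rank_invariant"}.
#' @param missing_fraction fraction of Ct wells set missing.
#' @param network_target network density target.
#' @param alpha_mix covariance mixing weight of the network stage.
#' @param alpha FDR level used by the screens.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 80,
                            sim = sim_config(p_genes = 20),
                            snp = snp_config(),
                            reference_gene = "REF1",
                            normalize_method = "dct",
                            missing_fraction = 0.01,
                            network_target = 0.15, alpha_mix = 0.5,
                            alpha = 0.05) {
  stopifnot(normalize_method %in% c("dct", "quantile", "rank_invariant"))
  structure(list(seed = seed, n_subjects = n_subjects, sim = sim,
                 snp = snp, reference_gene = reference_gene,
                 normalize_method = normalize_method,
                 missing_fraction = missing_fraction,
                 network_target = network_target, alpha_mix = alpha_mix,
                 alpha = alpha),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  config$seed * 10L + match(stage, c("simulate", "qpcr", "screen",
                                     "network", "eqtl"))
}

#' Run the full pipeline
#'
#' Executes simulate, normalize, screen, network and eqtl stages from one
#' configuration, writing every stage's outputs, a manifest and a run log
#' into \code{outdir}. Re-running with the same configuration and seed
#' reproduces all TSV outputs byte-identically. Any stage failure halts
#' with a stage-tagged error.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @return \code{outdir}, invisibly; side effect: the artifact directory.
#' @export
run_pipeline <- function(config, outdir, log_level = c("info", "quiet")) {
  stopifnot(inherits(config, "pipeline_config"))
  log_level <- match.arg(log_level)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  cat("", file = log_path)
  logmsg <- function(...) {
    line <- paste0("[", paste0(...), "]")
    cat(line, "\n", file = log_path, append = TRUE)
    if (log_level == "info") message(line)
  }
  run_stage <- function(stage, fn) {
    logmsg("stage ", stage, ": start")
    out <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logmsg("stage ", stage, ": done")
    out
  }

  # --- simulate -----------------------------------------------------------
  sim <- run_stage("simulate", function() {
    s <- stage_seed(config, "simulate")
    truth <- generate_truth(config$sim, seed = s)
    cohort <- generate_cohort(truth, config$n_subjects, seed = s)
    expr <- generate_expression(truth, cohort, seed = s)
    geno <- generate_genotypes(truth, cohort, config$snp, seed = s,
                               expr = expr)
    expr <- geno$expr
    # append a stable reference gene for delta-Ct normalization
    ref <- matrix(0, 1, ncol(expr$mat),
                  dimnames = list(config$reference_gene, NULL))
    expr2 <- expr_set(rbind(expr$mat, ref), expr$samples,
                      method = "simulated")
    ct <- generate_ct_plates(expr2, seed = s,
                             missing_fraction = config$missing_fraction)
    write_truth_json(truth, file.path(outdir, "truth.json"))
    write_cohort_tsv(cohort, file.path(outdir, "cohort.tsv"))
    write_ct_tsv(ct, file.path(outdir, "ct.tsv"))
    write_dose_tsv(geno, file.path(outdir, "doses.tsv"))
    write_vcf_minimal(geno, file.path(outdir, "genotypes.vcf"))
    write_gene_tsv(geno$genes, file.path(outdir, "genes.tsv"))
    list(truth = truth, cohort = cohort, ct = ct, geno = geno)
  })

  # --- qpcr ---------------------------------------------------------------
  expr <- run_stage("qpcr", function() {
    qc <- qc_filter_genes(sim$ct)
    e <- switch(config$normalize_method,
      dct = delta_ct_normalize(qc$ct, config$reference_gene),
      quantile = {
        cm <- ct_matrix(qc$ct)
        keep <- !cm$info$is_calibrator
        expr_set(quantile_normalize(-cm$mat)[, keep, drop = FALSE],
                 data.frame(column_id = cm$info$column_id[keep],
                            subject_id = cm$info$subject_id[keep],
                            cid = cm$info$cid[keep],
                            stringsAsFactors = FALSE),
                 method = "quantile")
      },
      rank_invariant = {
        cm <- ct_matrix(qc$ct)
        keep <- !cm$info$is_calibrator
        expr_set(rank_invariant_normalize(-cm$mat)[, keep, drop = FALSE],
                 data.frame(column_id = cm$info$column_id[keep],
                            subject_id = cm$info$subject_id[keep],
                            cid = cm$info$cid[keep],
                            stringsAsFactors = FALSE),
                 method = "rank_invariant")
      })
    # samples that lost their reference have no measurements at all; they
    # cannot be imputed and are dropped
    dead <- colSums(!is.na(e$mat)) == 0
    if (any(dead)) {
      e <- expr_set(e$mat[, !dead, drop = FALSE],
                    e$samples[!dead, , drop = FALSE],
                    method = e$method, reference = e$reference)
    }
    if (anyNA(e$mat)) e$mat <- knn_impute(e$mat, k = min(10, nrow(e$mat) - 1))
    jsonlite::write_json(list(removed = qc$report,
                              n_genes = nrow(e$mat),
                              method = config$normalize_method),
                         file.path(outdir, "qc_report.json"),
                         digits = NA, auto_unbox = TRUE)
    write_expression_tsv(e, file.path(outdir, "expression.tsv"))
    e
  })

  # --- screen -------------------------------------------------------------
  screen <- run_stage("screen", function() {
    pheno <- derive_phenotypes(sim$cohort)
    keep <- setdiff(rownames(expr$mat), config$reference_gene)
    expr <- expr_set(expr$mat[keep, , drop = FALSE], expr$samples,
                     method = expr$method, reference = expr$reference)
    fits <- fit_gene_lmm(expr, pheno,
                         design_spec("cid", c("centre", "subject")))
    ctr <- cid_contrasts(fits)
    pat <- classify_diet_patterns(ctr, alpha = config$alpha)
    sexfits <- fit_gene_lmm(expr, pheno,
                            design_spec(c("sex", "mets"), "centre",
                                        subset = "cid == 1"))
    sextab <- term_test(sexfits, "sex")
    write_tsv(ctr, file.path(outdir, "cid_contrasts.tsv"))
    write_tsv(pat, file.path(outdir, "diet_patterns.tsv"))
    write_tsv(sextab, file.path(outdir, "sex_screen.tsv"))
    list(pheno = pheno, contrasts = ctr, patterns = pat, sex = sextab)
  })

  # --- network ------------------------------------------------------------
  run_stage("network", function() {
    e1 <- expr_at_cid(expr, 1)
    genes <- setdiff(rownames(e1$mat), config$reference_gene)
    x <- t(e1$mat[genes, , drop = FALSE])
    sex <- screen$pheno$sex[match(e1$samples$subject_id,
                                  screen$pheno$subject_id)]
    nets <- infer_group_networks(x, sex, alpha_mix = config$alpha_mix,
                                 target = config$network_target)
    for (g in names(nets)) {
      export_network(nets[[g]],
                     file.path(outdir, paste0("network_", g, ".graphml")),
                     "graphml")
      export_network(nets[[g]],
                     file.path(outdir, paste0("network_", g, "_edges.tsv")),
                     "edgelist")
      write_tsv(data.frame(node = nets[[g]]$nodes,
                           degree = unname(nets[[g]]$degree),
                           betweenness = unname(nets[[g]]$betweenness)),
                file.path(outdir, paste0("network_", g, "_metrics.tsv")))
    }
    sh <- shared_edge_fraction(nets[[1]], nets[[2]])
    jsonlite::write_json(sh, file.path(outdir, "network_shared.json"),
                         digits = NA, auto_unbox = TRUE)
    nets
  })

  # --- eqtl ---------------------------------------------------------------
  run_stage("eqtl", function() {
    qc <- genotype_qc(sim$geno)
    pairs <- map_cis_pairs(qc$geno$snps, sim$geno$genes)
    res <- lapply(1:3, function(cid) {
      eqtl_screen(expr_at_cid(expr, cid), qc$geno, pairs, screen$pheno,
                  cid = cid)
    })
    pers <- eqtl_persistence(res[[1]], res[[2]], res[[3]],
                             alpha = config$alpha)
    for (cid in 1:3) {
      write_tsv(res[[cid]], file.path(outdir,
                                      sprintf("eqtl_cid%d.tsv", cid)))
    }
    write_tsv(qc$report, file.path(outdir, "genotype_qc.tsv"))
    write_tsv(pers, file.path(outdir, "eqtl_persistent.tsv"))
    res
  })

  manifest <- list(
    stages = c("simulate", "qpcr", "screen", "network", "eqtl"),
    seed = config$seed,
    n_subjects = config$n_subjects,
    p_genes = config$sim$p_genes,
    normalize_method = config$normalize_method,
    network_target = config$network_target,
    alpha_mix = config$alpha_mix,
    package_version = as.character(utils::packageVersion("dietexpr")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(outdir)
}

#' Validate pipeline interchange files
#'
#' Schema checks for the Ct TSV, cohort TSV, genotype dose TSV and gene
#' annotation TSV: required columns, value ranges (Ct in (0, 40] or the
#' sentinel 999, doses in 0/1/2), per-plate calibrator and water wells,
#' and duplicate (gene, sample, cid) detection within a set.
#'
#' @param paths named list with any of \code{ct}, \code{cohort},
#'   \code{doses}, \code{genes}.
#' @return list with \code{violations} (data.frame \code{file},
#'   \code{problem}) and \code{counts} (rows per file).
#' @export
validate_io <- function(paths) {
  violations <- data.frame(file = character(), problem = character(),
                           stringsAsFactors = FALSE)
  counts <- list()
  bad <- function(file, problem) {
    violations <<- rbind(violations,
                         data.frame(file = file, problem = problem,
                                    stringsAsFactors = FALSE))
  }
  if (!is.null(paths$ct)) {
    if (!file.exists(paths$ct)) {
      bad("ct", "file does not exist")
    } else {
      d <- read_ct_tsv(paths$ct)
      counts$ct <- nrow(d)
      need <- c("plate", "set", "well", "sample_id", "cid", "gene", "ct",
                "is_calibrator", "is_water")
      if (!all(need %in% colnames(d))) {
        bad("ct", paste("missing columns:",
                        paste(setdiff(need, colnames(d)), collapse = ", ")))
      } else {
        out_of_range <- d$ct != 999 & (d$ct <= 0 | d$ct > 40)
        if (any(out_of_range)) {
          bad("ct", sprintf("Ct out of range in %d well(s)",
                            sum(out_of_range)))
        }
        for (pl in unique(d$plate)) {
          dp <- d[d$plate == pl, ]
          if (!any(dp$is_calibrator)) {
            bad("ct", paste("plate", pl, "has no calibrator well"))
          }
          if (!any(dp$is_water)) {
            bad("ct", paste("plate", pl, "has no water well"))
          }
        }
        endo <- d[!d$is_calibrator & !d$is_water, ]
        key <- paste(endo$set, endo$gene, endo$sample_id, endo$cid)
        if (anyDuplicated(key)) {
          bad("ct", sprintf("duplicated (gene, sample, cid) in %d well(s)",
                            sum(duplicated(key))))
        }
      }
    }
  }
  if (!is.null(paths$cohort)) {
    if (!file.exists(paths$cohort)) {
      bad("cohort", "file does not exist")
    } else {
      d <- read_cohort_tsv(paths$cohort)
      counts$cohort <- nrow(d)
      need <- c("subject_id", "cid", "centre", "sex", "weight", "height")
      if (!all(need %in% colnames(d))) {
        bad("cohort", paste("missing columns:",
                            paste(setdiff(need, colnames(d)),
                                  collapse = ", ")))
      } else {
        if (any(d$weight <= 0, na.rm = TRUE)) bad("cohort",
                                                  "non-positive weight")
        if (!all(d$cid %in% 1:3)) bad("cohort", "cid outside 1..3")
      }
    }
  }
  if (!is.null(paths$doses)) {
    if (!file.exists(paths$doses)) {
      bad("doses", "file does not exist")
    } else {
      g <- read_dose_tsv(paths$doses)
      counts$doses <- nrow(g$doses)
      if (!all(g$doses %in% c(0L, 1L, 2L, NA))) {
        bad("doses", "dose outside {0, 1, 2, missing}")
      }
    }
  }
  if (!is.null(paths$genes)) {
    if (!file.exists(paths$genes)) {
      bad("genes", "file does not exist")
    } else {
      d <- read_gene_tsv(paths$genes)
      counts$genes <- nrow(d)
      if (any(d$cds_start > d$cds_end)) bad("genes", "cds_start > cds_end")
      if (any(!d$strand %in% c("+", "-"))) bad("genes", "unknown strand")
    }
  }
  list(violations = violations, counts = counts)
}
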