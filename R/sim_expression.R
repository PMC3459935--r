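#' Construct a log2 relative-expression set
#'
#' Light container pairing a genes-by-(sample, visit) matrix of log2 relative
#' expression with its sample annotation and normalization provenance.
#'
#' @param mat numeric matrix, genes in rows; column names are
#'   \code{<subject>_<cid>} keys.
#' @param samples data.frame with columns \code{column_id},
#'   \code{subject_id}, \code{cid} matching the matrix columns.
#' @param method,reference provenance: normalization method and reference
#'   gene (if any).
#' @return an object of class \code{expr_set}.
#' @export
expr_set <- function(mat, samples, method = "simulated", reference = NA) {
  stopifnot(is.matrix(mat), identical(colnames(mat), samples$column_id))
  structure(list(mat = mat, samples = samples, method = method,
                 reference = reference),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$mat), "genes x", ncol(x$mat), "sample-visits;",
      "method:", x$method,
      if (!is.na(x$reference)) paste0("(reference ", x$reference, ")"), "\n")
  invisible(x)
}

sample_key <- function(subject_id, cid) paste(subject_id, cid, sep = "_")

# Per-visit diet-phase shift for one regulation class.
diet_shift_at <- function(pattern, delta, cid) {
  shift <- numeric(length(pattern))
  if (cid == 2) {
    shift[pattern == "opposite_down_up"] <- -delta[pattern == "opposite_down_up"]
    shift[pattern == "opposite_up_down"] <- delta[pattern == "opposite_up_down"]
    shift[pattern == "end_down"] <- -delta[pattern == "end_down"] / 2
    shift[pattern == "end_up"] <- delta[pattern == "end_up"] / 2
  } else if (cid == 3) {
    shift[pattern == "end_down"] <- -delta[pattern == "end_down"]
    shift[pattern == "end_up"] <- delta[pattern == "end_up"]
  }
  shift
}

#' Generate log2 gene expression for a cohort
#'
#' Draws each subject's stable expression profile once from the subject's
#' sex-group Gaussian graphical model (the GGM describes between-subject
#' covariation of adipose expression), then builds each visit's
#' observation by adding the truth's fixed effects (sex fold change, BMI
#' slope on the visit's BMI, metabolic-syndrome shift from the baseline
#' visit, diet-phase shift by regulation class), centre and subject random
#' intercepts, and per-visit residual noise. Because the biological
#' profile is shared across visits, within-subject change scores carry
#' only the visit effects plus measurement noise. Setting the effect maps
#' and variance components to zero makes the output the raw GGM draw.
#'
#' @param truth a \code{sim_truth}.
#' @param cohort a cohort table from [generate_cohort()].
#' @param seed integer seed.
#' @param bmi_center BMI value at which the BMI effect is zero.
#' @return an [expr_set()] covering all three visits.
#' @export
generate_expression <- function(truth, cohort, seed = 1, bmi_center = 35) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  genes <- truth$genes
  p <- length(genes)
  subjects <- unique(cohort$subject_id)
  base <- cohort[cohort$cid == 1, ]
  base <- base[match(subjects, base$subject_id), ]
  mets0 <- classify_mets(base$waist, base$tg, base$hdl, base$sbp, base$dbp,
                         base$glucose, base$sex)
  mets0[is.na(mets0)] <- FALSE

  chol_by_group <- lapply(truth$precision,
                          function(th) chol(solve(th)))
  centres <- sort(unique(cohort$centre))
  centre_int <- matrix(stats::rnorm(length(centres) * p, 0, truth$centre_sd),
                       nrow = p, dimnames = list(genes, centres))
  subject_int <- matrix(stats::rnorm(length(subjects) * p, 0,
                                     truth$subject_sd),
                        nrow = p, dimnames = list(genes, subjects))

  # one stable biological profile per subject
  sex_of <- cohort$sex[match(subjects, cohort$subject_id)]
  z_subject <- matrix(NA_real_, p, length(subjects),
                      dimnames = list(genes, subjects))
  for (i in seq_along(subjects)) {
    z_subject[, i] <- drop(stats::rnorm(p) %*% chol_by_group[[sex_of[i]]])
  }

  cols <- sample_key(cohort$subject_id, cohort$cid)
  mat <- matrix(NA_real_, p, nrow(cohort), dimnames = list(genes, cols))
  bmi <- cohort$weight / cohort$height^2
  for (r in seq_len(nrow(cohort))) {
    sx <- cohort$sex[r]
    sid <- cohort$subject_id[r]
    mu <- z_subject[, sid] + truth$gene_mean +
      truth$sex_effect * (sx == "F") +
      truth$bmi_slope * (bmi[r] - bmi_center) +
      truth$mets_shift * mets0[match(sid, subjects)] +
      diet_shift_at(truth$diet_pattern, truth$diet_shift, cohort$cid[r]) +
      centre_int[, as.character(cohort$centre[r])] +
      subject_int[, sid]
    mat[, r] <- mu + stats::rnorm(p, 0, truth$noise_sd)
  }
  samples <- data.frame(column_id = cols, subject_id = cohort$subject_id,
                        cid = cohort$cid, stringsAsFactors = FALSE)
  expr_set(mat, samples, method = "simulated")
}

#' Subset an expression set to one visit
#'
#' @param expr an \code{expr_set}.
#' @param cid visit number (1, 2 or 3).
#' @return an \code{expr_set} whose columns are the requested visit, ordered
#'   by subject.
#' @export
expr_at_cid <- function(expr, cid) {
  keep <- expr$samples$cid == cid
  s <- expr$samples[keep, , drop = FALSE]
  o <- order(s$subject_id)
  s <- s[o, , drop = FALSE]
  rownames(s) <- NULL
  expr_set(expr$mat[, s$column_id, drop = FALSE], s,
           method = expr$method, reference = expr$reference)
}
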