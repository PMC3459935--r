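# Long Ct set -> genes x sample matrix of raw Ct (999 -> NA).
# Calibrator wells become one pseudo-sample per plate ("CAL_p<plate>");
# water wells are dropped.
ct_matrix <- function(ct) {
  d <- ct[!ct$is_water, ]
  key <- ifelse(d$is_calibrator, paste0("CAL_p", d$plate),
                sample_key(d$sample_id, d$cid))
  genes <- unique(d$gene)
  cols <- unique(key)
  m <- matrix(NA_real_, length(genes), length(cols),
              dimnames = list(genes, cols))
  m[cbind(match(d$gene, genes), match(key, cols))] <-
    ifelse(d$ct == 999, NA_real_, d$ct)
  info <- data.frame(column_id = cols,
                     subject_id = sub("_[0-9]+$", "", cols),
                     cid = suppressWarnings(
                       as.integer(sub("^.*_", "", cols))),
                     is_calibrator = startsWith(cols, "CAL_p"),
                     stringsAsFactors = FALSE)
  info$subject_id[info$is_calibrator] <- "CAL"
  list(mat = m, info = info)
}

#' Delta-Ct normalization against a reference gene
#'
#' Computes log2 relative expression as \code{-(Ct_gene - Ct_reference)}
#' within each sample-visit (equivalently, relative expression
#' \code{2^-deltaCt}). Because gene and reference are measured on the same
#' plate, any per-plate additive Ct shift cancels. Sentinel/missing Ct
#' propagates as \code{NA}; a sample whose reference Ct is missing is
#' flagged missing for every gene.
#'
#' @param ct a Ct set (long data.frame).
#' @param reference_gene reference gene id (e.g. \code{"GUSB"}).
#' @param keep_calibrator keep the per-plate calibrator pseudo-samples as
#'   columns (used by [calibrator_cv()]).
#' @return an [expr_set()] of log2 relative expression (the reference gene
#'   row is retained and is identically zero where measured).
#' @export
delta_ct_normalize <- function(ct, reference_gene,
                               keep_calibrator = FALSE) {
  cm <- ct_matrix(ct)
  if (!reference_gene %in% rownames(cm$mat)) {
    stop("reference gene ", reference_gene, " not present in the Ct set")
  }
  ref <- cm$mat[reference_gene, ]
  m <- -sweep(cm$mat, 2, ref, "-")
  m[, is.na(ref)] <- NA_real_
  if (!keep_calibrator) {
    keep <- !cm$info$is_calibrator
    m <- m[, keep, drop = FALSE]
    cm$info <- cm$info[keep, , drop = FALSE]
  }
  samples <- data.frame(column_id = cm$info$column_id,
                        subject_id = cm$info$subject_id,
                        cid = cm$info$cid, stringsAsFactors = FALSE)
  expr_set(m, samples, method = "dct", reference = reference_gene)
}

#' Quantile normalization
#'
#' Forces every column (sample) of the matrix to the same empirical
#' distribution, the row-wise mean of the column-sorted input; corrects
#' additive/column-wise (inter-plate) shifts. Ties share the mean of their
#' tied quantiles; missing entries are excluded from rank computation and
#' stay missing.
#'
#' @param m numeric matrix, samples as columns.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2)
  if (any(colSums(!is.na(m)) == 0)) stop("column entirely missing")
  limma::normalizeQuantiles(m, ties = TRUE)
}

#' Rank-invariant normalization
#'
#' For each column, finds the genes whose within-column rank differs from
#' their rank in a reference profile by at most \code{rank_tol} of the gene
#' count (the rank-invariant set), fits a smooth monotone mapping from the
#' column to the reference through that set (lowess), and applies it to the
#' whole column.
#'
#' @param m numeric matrix, genes x samples.
#' @param reference_profile reference column; defaults to the row-wise
#'   median pseudo-sample.
#' @param rank_tol allowed rank difference as a fraction of the gene count.
#' @param min_invariant minimum invariant-set size; fewer is an error.
#' @param f lowess smoother span.
#' @return normalized matrix.
#' @export
rank_invariant_normalize <- function(m, reference_profile = NULL,
                                     rank_tol = 0.05, min_invariant = 5,
                                     f = 2 / 3) {
  stopifnot(is.matrix(m))
  if (is.null(reference_profile)) {
    reference_profile <- apply(m, 1, stats::median, na.rm = TRUE)
  }
  stopifnot(length(reference_profile) == nrow(m))
  out <- m
  r_ref <- rank(reference_profile, na.last = "keep")
  tol <- rank_tol * nrow(m)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x) & !is.na(reference_profile)
    r_x <- rank(x, na.last = "keep")
    inv <- ok & abs(r_x - r_ref) <= tol
    if (sum(inv) < min_invariant) {
      stop("rank-invariant set too small in column ", j, " (",
           sum(inv), " genes)")
    }
    fit <- stats::lowess(x[inv], reference_profile[inv], f = f)
    out[, j] <- stats::approx(fit$x, fit$y, xout = x, rule = 2,
                              ties = mean)$y
  }
  out
}

#' Compare normalization methods by calibrator coefficient of variation
#'
#' The calibrator sample is the same cDNA run on every plate, so after a
#' perfect normalization its expression profile is constant across plates.
#' For each method this computes the per-gene coefficient of variation
#' (SD/mean on the linear expression scale) of the calibrator across
#' plates and reports the mean over genes, with the raw (unnormalized)
#' data as baseline.
#'
#' @param ct a Ct set with calibrator wells on at least 2 plates.
#' @param methods subset of \code{c("raw", "dct", "quantile",
#'   "rank_invariant")}.
#' @param reference_gene reference gene for the delta-Ct method.
#' @return data.frame \code{method}, \code{cv} (mean per-gene CV).
#' @export
calibrator_cv <- function(ct, methods = c("raw", "dct", "quantile",
                                          "rank_invariant"),
                          reference_gene = NULL) {
  known <- c("raw", "dct", "quantile", "rank_invariant")
  if (!all(methods %in% known)) {
    stop("unknown method(s): ",
         paste(setdiff(methods, known), collapse = ", "))
  }
  cm <- ct_matrix(ct)
  cal_cols <- cm$info$column_id[cm$info$is_calibrator]
  if (length(cal_cols) < 2) stop("calibrator measured on < 2 plates")

  cv_of <- function(log2_mat) {
    lin <- 2^log2_mat[, cal_cols, drop = FALSE]
    cvs <- apply(lin, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2 || mean(v) == 0) return(NA_real_)
      stats::sd(v) / mean(v)
    })
    mean(cvs, na.rm = TRUE)
  }
  res <- lapply(methods, function(meth) {
    x <- switch(meth,
      raw = -cm$mat,
      dct = {
        if (is.null(reference_gene)) {
          stop("reference_gene required for the dct method")
        }
        delta_ct_normalize(ct, reference_gene, keep_calibrator = TRUE)$mat
      },
      quantile = quantile_normalize(-cm$mat),
      rank_invariant = rank_invariant_normalize(-cm$mat))
    data.frame(method = meth, cv = cv_of(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
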