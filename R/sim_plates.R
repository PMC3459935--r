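#' Assign sample-visits to qPCR plates
#'
#' Splits the columns of an expression set over plates, each of which also
#' carries one calibrator well block and one water-control well, mirroring a
#' microfluidic qPCR design where the same calibrator cDNA is run on every
#' plate.
#'
#' @param expr an \code{expr_set}.
#' @param samples_per_plate sample-visits per plate (calibrator and water
#'   wells come on top).
#' @param set gene-set label for the plates.
#' @return data.frame with columns \code{column_id}, \code{plate},
#'   \code{set}.
#' @export
make_plate_design <- function(expr, samples_per_plate = 46, set = "A") {
  ids <- expr$samples$column_id
  plate <- ((seq_along(ids) - 1L) %/% samples_per_plate) + 1L
  data.frame(column_id = ids, plate = plate, set = set,
             stringsAsFactors = FALSE)
}

#' Generate raw qPCR Ct plates from expression
#'
#' Inverts the delta-Ct relation: \code{Ct(gene, well) = ct_baseline -
#' log2(relative expression) + plate offset + well noise}. Each plate also
#' gets calibrator wells that replicate one fixed expression profile across
#' all plates, and a water-control well at the missing sentinel. A
#' configured fraction of wells is set to the sentinel 999 (absent
#' amplification) and a configured gene subset is forced above the
#' high-Ct exclusion threshold via an elevated baseline.
#'
#' @param expr an \code{expr_set} of true log2 relative expression.
#' @param plate_design from [make_plate_design()]; defaults to
#'   \code{make_plate_design(expr)}.
#' @param seed integer seed.
#' @param ct_baseline Ct corresponding to relative expression 1.
#' @param plate_offset_sd SD of the per-plate additive Ct offset.
#' @param well_noise_sd SD of per-well Ct noise.
#' @param missing_fraction fraction of (non-water) wells set to 999.
#' @param high_ct_genes genes forced to Ct > 30 (baseline set to 35).
#' @param calibrator_profile optional named log2-expression vector for the
#'   calibrator sample; drawn N(0, 1) per gene by default.
#' @return a long-format \code{data.frame} (the Ct set) with columns
#'   \code{plate}, \code{set}, \code{well}, \code{sample_id}, \code{cid},
#'   \code{gene}, \code{ct}, \code{is_calibrator}, \code{is_water}; the
#'   calibrator profile is attached as attribute
#'   \code{"calibrator_profile"}.
#' @export
generate_ct_plates <- function(expr, plate_design = NULL, seed = 1,
                               ct_baseline = 20, plate_offset_sd = 0.3,
                               well_noise_sd = 0.15, missing_fraction = 0,
                               high_ct_genes = character(),
                               calibrator_profile = NULL) {
  set.seed(seed)
  if (is.null(plate_design)) plate_design <- make_plate_design(expr)
  stopifnot(all(expr$samples$column_id %in% plate_design$column_id))
  genes <- rownames(expr$mat)
  base <- stats::setNames(rep(ct_baseline, length(genes)), genes)
  base[intersect(high_ct_genes, genes)] <- 35
  if (is.null(calibrator_profile)) {
    calibrator_profile <- stats::setNames(stats::rnorm(length(genes)), genes)
  }
  plates <- sort(unique(plate_design$plate))
  offset <- stats::setNames(stats::rnorm(length(plates), 0, plate_offset_sd),
                            plates)

  rows <- vector("list", length(plates))
  for (pi in seq_along(plates)) {
    pl <- plates[pi]
    cols <- plate_design$column_id[plate_design$plate == pl]
    st <- plate_design$set[plate_design$plate == pl][1]
    smp <- expr$samples[match(cols, expr$samples$column_id), ]
    ng <- length(genes)
    # endogenous sample wells
    x <- expr$mat[, cols, drop = FALSE]
    ct_s <- base - x + offset[as.character(pl)] +
      matrix(stats::rnorm(length(x), 0, well_noise_sd), nrow = ng)
    # calibrator block + water control
    ct_c <- base - calibrator_profile + offset[as.character(pl)] +
      stats::rnorm(ng, 0, well_noise_sd)
    rows[[pi]] <- data.frame(
      plate = pl, set = st,
      well = c(rep(seq_along(cols), each = ng),
               rep(length(cols) + 1L, ng), rep(length(cols) + 2L, ng)),
      sample_id = c(rep(smp$subject_id, each = ng),
                    rep("CAL", ng), rep("H2O", ng)),
      cid = c(rep(smp$cid, each = ng), rep(NA_integer_, 2L * ng)),
      gene = rep(genes, length(cols) + 2L),
      ct = c(as.vector(ct_s), ct_c, rep(999, ng)),
      is_calibrator = c(rep(FALSE, ng * length(cols)),
                        rep(TRUE, ng), rep(FALSE, ng)),
      is_water = c(rep(FALSE, ng * (length(cols) + 1L)), rep(TRUE, ng)),
      stringsAsFactors = FALSE
    )
  }
  ct <- do.call(rbind, rows)
  if (missing_fraction > 0) {
    cand <- which(!ct$is_water)
    drop <- cand[stats::runif(length(cand)) < missing_fraction]
    ct$ct[drop] <- 999
  }
  attr(ct, "calibrator_profile") <- calibrator_profile
  attr(ct, "ct_baseline") <- base
  ct
}
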