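#' Generate a three-visit dietary-intervention cohort table
#'
#' Simulates subject-by-visit clinical records for a multi-centre weight-loss
#' trial with three clinical investigation days: CID1 (baseline), CID2 (end
#' of the 8-week low-calorie diet) and CID3 (end of the 26-week
#' weight-maintenance diet). Every subject loses at least the LCD target
#' fraction of body weight by CID2; at CID3 the cohort splits into subjects
#' who regain, who keep losing, and who stay near their CID2 weight, so that
#' weight-change groups are always populated. Cardiometabolic variables
#' (waist, blood pressure, lipids, glycaemia, adipokines) load on a single
#' latent metabolic-syndrome factor per subject and track weight across
#' visits.
#'
#' @param truth a \code{sim_truth} (carried along for provenance; clinical
#'   variables do not depend on the gene-level truth).
#' @param n_subjects number of subjects (at least 4).
#' @param seed integer seed.
#' @param n_centres number of study centres.
#' @param female_frac fraction of women.
#' @param mean_lcd_loss mean fractional weight loss over the LCD (the trial
#'   target); with \code{lcd_loss_sd = 0} every CID2 weight equals
#'   \code{(1 - mean_lcd_loss)} times baseline.
#' @param lcd_loss_sd SD of the extra (always non-negative) LCD loss beyond
#'   the target.
#' @param regain_fraction probability that a subject regains at least half of
#'   the lost weight by CID3.
#' @return a \code{data.frame} with one row per (subject, cid): columns
#'   \code{subject_id}, \code{cid}, \code{centre}, \code{sex}, \code{diet},
#'   \code{weight}, \code{height}, \code{waist}, \code{fat_mass},
#'   \code{sbp}, \code{dbp}, \code{tg}, \code{hdl}, \code{glucose},
#'   \code{insulin}, \code{crp}, \code{adiponectin}, \code{completer}.
#' @export
generate_cohort <- function(truth, n_subjects, seed = 1, n_centres = 8,
                            female_frac = 0.65, mean_lcd_loss = 0.08,
                            lcd_loss_sd = 0.02, regain_fraction = 0.5) {
  if (n_subjects < 4) stop("n_subjects < 4: cannot populate the design")
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n_subjects))
  n_f <- round(female_frac * n_subjects)
  sex <- sample(c(rep("F", n_f), rep("M", n_subjects - n_f)))
  # round-robin centres within sex so centre x sex cells stay populated
  centre <- integer(n_subjects)
  for (s in c("M", "F")) {
    k <- which(sex == s)
    centre[k] <- rep_len(seq_len(n_centres), length(k))
  }
  diet <- sample(1:5, n_subjects, replace = TRUE)
  height <- ifelse(sex == "M", stats::rnorm(n_subjects, 1.77, 0.06),
                   stats::rnorm(n_subjects, 1.65, 0.06))
  # obese baseline: BMI roughly 30-42
  bmi1 <- stats::runif(n_subjects, 30, 42)
  w1 <- bmi1 * height^2

  loss_frac <- mean_lcd_loss + abs(stats::rnorm(n_subjects, 0, lcd_loss_sd))
  w2 <- w1 * (1 - loss_frac)
  lost <- w1 - w2

  grp <- stats::runif(n_subjects)
  u <- numeric(n_subjects)
  is_regain <- grp < regain_fraction
  is_loss <- !is_regain & grp < regain_fraction + (1 - regain_fraction) / 2
  u[is_regain] <- stats::runif(sum(is_regain), 0.5, 1.1)
  u[is_loss] <- stats::runif(sum(is_loss), -1.0, -0.5)
  rest <- !is_regain & !is_loss
  u[rest] <- stats::runif(sum(rest), -0.45, 0.45)
  w3 <- w2 + u * lost

  f <- stats::rnorm(n_subjects)  # latent metabolic-syndrome factor

  one_visit <- function(cid, w) {
    dw <- w - w1  # weight change from baseline drags risk factors along
    data.frame(
      subject_id = ids, cid = cid, centre = centre, sex = sex, diet = diet,
      weight = w, height = height,
      waist = ifelse(sex == "M", 58, 48) + 0.45 * w + 5 * f +
        stats::rnorm(n_subjects, 0, 3),
      fat_mass = ifelse(sex == "M", 30, 42) + 3 * f + 0.15 * dw +
        stats::rnorm(n_subjects, 0, 3),
      sbp = 127 + 8 * f + 0.3 * dw + stats::rnorm(n_subjects, 0, 8),
      dbp = 81 + 5 * f + 0.2 * dw + stats::rnorm(n_subjects, 0, 5),
      tg = pmax(0.3, exp(log(1.5) + 0.30 * f + 0.01 * dw +
                           stats::rnorm(n_subjects, 0, 0.20))),
      hdl = pmax(0.4, 1.25 - 0.15 * f - 0.005 * dw +
                   stats::rnorm(n_subjects, 0, 0.15)),
      glucose = pmax(3.5, 5.5 + 0.5 * f + 0.03 * dw +
                       stats::rnorm(n_subjects, 0, 0.35)),
      insulin = pmax(1, exp(log(12) + 0.40 * f + 0.02 * dw +
                              stats::rnorm(n_subjects, 0, 0.30))),
      crp = exp(log(3) + 0.30 * f + stats::rnorm(n_subjects, 0, 0.5)),
      adiponectin = exp(log(8) - 0.30 * f + stats::rnorm(n_subjects, 0, 0.3)),
      completer = loss_frac > 0,
      stringsAsFactors = FALSE
    )
  }
  cohort <- rbind(one_visit(1L, w1), one_visit(2L, w2), one_visit(3L, w3))
  cohort <- cohort[order(cohort$subject_id, cohort$cid), ]
  rownames(cohort) <- NULL
  cohort
}
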