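#' Simulation configuration for a dietary-intervention cohort
#'
#' Bundles the generative parameters used by [generate_truth()] and the
#' downstream generators. Defaults describe a three-visit multi-centre
#' weight-loss trial: a panel of qPCR-profiled adipose-tissue genes whose
#' joint distribution follows sex-specific sparse Gaussian graphical models,
#' with sex, BMI, metabolic-syndrome and diet-phase fixed effects layered on
#' top, and centre/subject random intercepts.
#'
#' @param p_genes number of genes in the panel.
#' @param density target edge density of each group's precision support
#'   (edges / node pairs).
#' @param shared_fraction fraction of each group's edges shared between the
#'   two groups.
#' @param edge_range magnitude range of off-diagonal precision entries before
#'   diagonal loading.
#' @param sex_effect_frac,sex_effect_range fraction of genes with a sex effect
#'   and the magnitude range of the log2 fold change (female - male).
#' @param bmi_slope_frac,bmi_slope_range fraction of genes with a BMI slope
#'   and its magnitude range (log2 units per BMI unit).
#' @param diet_fractions named fractions of genes per diet-regulation class;
#'   must include \code{opposite_down_up}, \code{opposite_up_down},
#'   \code{end_down}, \code{end_up}; the remainder is null.
#' @param diet_shift_range magnitude range of the diet-phase shift (log2).
#' @param mets_frac,mets_shift_range fraction of genes shifted in
#'   metabolic-syndrome subjects and the magnitude range (log2).
#' @param eqtl_frac,eqtl_beta_range fraction of genes carrying a cis eQTL and
#'   the per-minor-allele effect range (log2 per allele).
#' @param gene_mean_range range of baseline mean log2 relative expression
#'   across genes (abundance spread of the panel).
#' @param noise_sd residual measurement noise SD (log2 units).
#' @param centre_sd,subject_sd random-intercept SDs for centre and subject.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(p_genes = 40,
                       density = 0.15,
                       shared_fraction = 0.75,
                       edge_range = c(0.2, 0.5),
                       sex_effect_frac = 0.2,
                       sex_effect_range = c(0.4, 1.0),
                       bmi_slope_frac = 0.2,
                       bmi_slope_range = c(0.02, 0.08),
                       diet_fractions = c(opposite_down_up = 0.20,
                                          opposite_up_down = 0.10,
                                          end_down = 0.10,
                                          end_up = 0.10),
                       diet_shift_range = c(0.3, 0.7),
                       mets_frac = 0.15,
                       mets_shift_range = c(0.2, 0.6),
                       eqtl_frac = 0.25,
                       eqtl_beta_range = c(0.3, 0.6),
                       gene_mean_range = c(-4, 4),
                       noise_sd = 0.25,
                       centre_sd = 0.15,
                       subject_sd = 0.30) {
  stopifnot(p_genes >= 2, density >= 0, density <= 1,
            shared_fraction >= 0, shared_fraction <= 1,
            sum(diet_fractions) <= 1)
  cfg <- list(p_genes = p_genes, density = density,
              shared_fraction = shared_fraction, edge_range = edge_range,
              sex_effect_frac = sex_effect_frac,
              sex_effect_range = sex_effect_range,
              bmi_slope_frac = bmi_slope_frac,
              bmi_slope_range = bmi_slope_range,
              diet_fractions = diet_fractions,
              diet_shift_range = diet_shift_range,
              mets_frac = mets_frac, mets_shift_range = mets_shift_range,
              eqtl_frac = eqtl_frac, eqtl_beta_range = eqtl_beta_range,
              gene_mean_range = gene_mean_range,
              noise_sd = noise_sd, centre_sd = centre_sd,
              subject_sd = subject_sd)
  class(cfg) <- "sim_config"
  cfg
}

# Build a symmetric precision matrix from an edge index set with diagonal
# loading: entries on the selected pairs, zero diagonal, then add
# (|lambda_min| + 0.1) to the diagonal so the result is positive definite.
build_precision <- function(p, edge_idx, values, genes) {
  a <- matrix(0, p, p, dimnames = list(genes, genes))
  if (length(edge_idx)) {
    ut <- which(upper.tri(a))
    a[ut[edge_idx]] <- values
    a <- a + t(a)
  }
  lam_min <- min(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  theta <- a + diag(abs(lam_min) + 0.1, p)
  if (min(eigen(theta, symmetric = TRUE,
                only.values = TRUE)$values) <= 0) {
    stop("internal failure: precision matrix not positive definite ",
         "after diagonal loading")
  }
  # rescale to unit marginal variances (log2 expression SD of 1); this
  # preserves the support and the partial correlations exactly
  d <- sqrt(diag(solve(theta)))
  theta <- theta * outer(d, d)
  dimnames(theta) <- list(genes, genes)
  theta
}

# Map linear upper-triangle indices to (i, j) node pairs.
pair_index_table <- function(p) {
  ut <- which(upper.tri(diag(p)), arr.ind = TRUE)
  ut[order(ut[, 2], ut[, 1]), , drop = FALSE]
}

#' Draw the ground truth of a simulated cohort
#'
#' Samples the generative parameters that every downstream generator and all
#' recovery tests share: two sparse precision matrices (one per sex group)
#' whose supports are Erdos-Renyi draws at the target density with a stated
#' fraction of edges in common, plus per-gene fixed-effect maps (sex, BMI,
#' metabolic syndrome, diet-phase pattern), cis-eQTL effects and the
#' variance components of the measurement model.
#'
#' Positive definiteness is enforced by diagonal loading: the sampled
#' zero-diagonal edge matrix gets \code{|lambda_min| + 0.1} added to its
#' diagonal.
#'
#' @param config a [sim_config()] list.
#' @param seed integer seed; the truth is a pure function of
#'   \code{(config, seed)}.
#' @return a list of class \code{sim_truth} with elements \code{genes},
#'   \code{precision} (list \code{M}, \code{F}), \code{shared_edges}
#'   (two-column matrix of node indices), \code{sex_effect},
#'   \code{bmi_slope}, \code{diet_pattern}, \code{diet_shift},
#'   \code{mets_shift}, \code{eqtl_beta} (all named by gene),
#'   \code{noise_sd}, \code{centre_sd}, \code{subject_sd}, \code{config}.
#' @export
generate_truth <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  p <- config$p_genes
  genes <- sprintf("G%03d", seq_len(p))
  n_pairs <- p * (p - 1L) / 2L
  n_edges <- round(config$density * n_pairs)
  n_shared <- round(config$shared_fraction * n_edges)
  n_uniq <- n_edges - n_shared

  perm <- sample.int(n_pairs)
  shared <- perm[seq_len(n_shared)]
  rest <- perm[-seq_len(n_shared)]
  uniq_m <- if (n_uniq) rest[seq_len(n_uniq)] else integer(0)
  uniq_f <- if (n_uniq) rest[n_uniq + seq_len(n_uniq)] else integer(0)

  draw_vals <- function(k) {
    if (!k) return(numeric(0))
    stats::runif(k, config$edge_range[1], config$edge_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
  }
  v_shared <- draw_vals(n_shared)
  prec <- list(
    M = build_precision(p, c(shared, uniq_m),
                        c(v_shared, draw_vals(n_uniq)), genes),
    F = build_precision(p, c(shared, uniq_f),
                        c(v_shared, draw_vals(n_uniq)), genes)
  )
  ptab <- pair_index_table(p)
  shared_edges <- ptab[sort(shared), , drop = FALSE]

  draw_map <- function(frac, range) {
    on <- stats::runif(p) < frac
    mag <- stats::runif(p, range[1], range[2]) *
      sample(c(-1, 1), p, replace = TRUE)
    stats::setNames(ifelse(on, mag, 0), genes)
  }
  sex_effect <- draw_map(config$sex_effect_frac, config$sex_effect_range)
  bmi_slope <- draw_map(config$bmi_slope_frac, config$bmi_slope_range)
  mets_shift <- draw_map(config$mets_frac, config$mets_shift_range)

  classes <- c(names(config$diet_fractions), "null")
  probs <- c(config$diet_fractions, null = 1 - sum(config$diet_fractions))
  diet_pattern <- stats::setNames(
    sample(classes, p, replace = TRUE, prob = probs), genes)
  diet_shift <- stats::setNames(
    stats::runif(p, config$diet_shift_range[1], config$diet_shift_range[2]),
    genes)
  diet_shift[diet_pattern == "null"] <- 0

  eqtl_on <- stats::runif(p) < config$eqtl_frac
  eqtl_beta <- stats::setNames(
    ifelse(eqtl_on,
           stats::runif(p, config$eqtl_beta_range[1],
                        config$eqtl_beta_range[2]) *
             sample(c(-1, 1), p, replace = TRUE),
           0),
    genes)

  gene_mean <- stats::setNames(
    stats::runif(p, config$gene_mean_range[1], config$gene_mean_range[2]),
    genes)

  out <- list(genes = genes, precision = prec, shared_edges = shared_edges,
              gene_mean = gene_mean,
              sex_effect = sex_effect, bmi_slope = bmi_slope,
              diet_pattern = diet_pattern, diet_shift = diet_shift,
              mets_shift = mets_shift, eqtl_beta = eqtl_beta,
              noise_sd = config$noise_sd, centre_sd = config$centre_sd,
              subject_sd = config$subject_sd, config = config)
  class(out) <- "sim_truth"
  out
}

#' Edge support of a precision matrix
#'
#' @param theta symmetric matrix.
#' @param tol entries with absolute value above \code{tol} count as edges.
#' @return two-column matrix of upper-triangle index pairs.
#' @export
precision_support <- function(theta, tol = 1e-10) {
  idx <- which(abs(theta) > tol & upper.tri(theta), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Draw observations from one group's Gaussian graphical model
#'
#' @param truth a \code{sim_truth}.
#' @param group \code{"M"} or \code{"F"}.
#' @param n number of observations.
#' @return an \code{n x p} matrix with gene column names.
#' @export
draw_ggm <- function(truth, group = c("M", "F"), n) {
  group <- match.arg(group)
  sigma <- solve(truth$precision[[group]])
  x <- MASS::mvrnorm(n, mu = rep(0, ncol(sigma)), Sigma = sigma)
  colnames(x) <- truth$genes
  x
}
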