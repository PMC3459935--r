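# Shared builders for small simulated fixtures.

# Truth with every fixed effect switched off (pure GGM + variance components).
null_config <- function(p = 10, density = 0.15, ...) {
  sim_config(p_genes = p, density = density,
             sex_effect_frac = 0, bmi_slope_frac = 0, mets_frac = 0,
             diet_fractions = c(opposite_down_up = 0, opposite_up_down = 0,
                                end_down = 0, end_up = 0),
             eqtl_frac = 0, gene_mean_range = c(0, 0), ...)
}

# Truth with no randomness beyond the GGM draw.
noiseless <- function(truth) {
  truth$noise_sd <- 0
  truth$centre_sd <- 0
  truth$subject_sd <- 0
  truth
}

# Expression set with a constant-zero reference gene appended, as delta-Ct
# normalization expects.
with_reference <- function(expr, name = "REF") {
  ref <- matrix(0, 1, ncol(expr$mat), dimnames = list(name, NULL))
  expr_set(rbind(expr$mat, ref), expr$samples, method = expr$method)
}

# Edge set of a support matrix as "i j" keys.
edge_key <- function(idx) paste(idx[, 1], idx[, 2])

# F1 between an inferred adjacency and a truth precision support.
edge_f1 <- function(adjacency, theta) {
  est <- edge_key(which(adjacency & upper.tri(adjacency), arr.ind = TRUE))
  tru <- edge_key(precision_support(theta))
  tp <- length(intersect(est, tru))
  2 * tp / (length(est) + length(tru))
}

# Brute-force BH step-up oracle: largest k with p_(k) <= k/m * alpha rejects
# p_(1..k); adjusted values by direct minimax definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- match(i, o)
    q[i] <- min(1, min(vapply(rank_i:m, function(k) m * p[o[k]] / k, 0)))
  }
  q
}
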