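test_that("truth supports have the configured edge count and sharing", {
  tt <- generate_truth(sim_config(p_genes = 40, density = 0.15,
                                  shared_fraction = 0.75), seed = 1)
  n_pairs <- 40 * 39 / 2
  expect_equal(nrow(precision_support(tt$precision$M)),
               round(0.15 * n_pairs))  # 117
  expect_equal(nrow(precision_support(tt$precision$F)),
               round(0.15 * n_pairs))
  expect_equal(nrow(tt$shared_edges), round(0.75 * 117))
  # shared edges are a subset of each group's support
  for (g in c("M", "F")) {
    sup <- edge_key(precision_support(tt$precision[[g]]))
    expect_true(all(edge_key(tt$shared_edges) %in% sup))
  }
  # positive definite
  for (g in c("M", "F")) {
    expect_gt(min(eigen(tt$precision[[g]], symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  # every gene in exactly one diet class
  expect_true(all(tt$diet_pattern %in%
                    c("opposite_down_up", "opposite_up_down", "end_down",
                      "end_up", "null")))
})

test_that("zero density gives a diagonal precision with no edges", {
  tt <- generate_truth(sim_config(p_genes = 8, density = 0), seed = 3)
  expect_equal(nrow(precision_support(tt$precision$M)), 0)
  rho <- partial_correlation(tt$precision$M)
  expect_equal(max(abs(rho[upper.tri(rho)])), 0)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(p_genes = 12)
  t1 <- generate_truth(cfg, seed = 9)
  t2 <- generate_truth(cfg, seed = 9)
  expect_identical(t1, t2)
  c1 <- generate_cohort(t1, 20, seed = 4)
  c2 <- generate_cohort(t1, 20, seed = 4)
  expect_identical(c1, c2)
  e1 <- generate_expression(t1, c1, seed = 5)
  e2 <- generate_expression(t1, c1, seed = 5)
  expect_identical(e1, e2)
  g1 <- generate_genotypes(t1, c1, seed = 6)
  g2 <- generate_genotypes(t1, c1, seed = 6)
  expect_identical(g1, g2)
})

test_that("cohort structure follows the three-visit design", {
  tt <- generate_truth(sim_config(p_genes = 5), seed = 2)
  co <- generate_cohort(tt, 200, seed = 7)
  expect_equal(nrow(co), 600)
  expect_equal(sort(unique(co$cid)), 1:3)
  # sex / height / centre constant within subject
  for (v in c("sex", "height", "centre", "diet")) {
    expect_true(all(tapply(co[[v]], co$subject_id,
                           function(x) length(unique(x))) == 1))
  }
  expect_true(all(co$weight > 0))
  # LCD weight loss for completers
  w <- reshape(co[, c("subject_id", "cid", "weight")],
               idvar = "subject_id", timevar = "cid", direction = "wide")
  expect_true(all(w$weight.2 < w$weight.1))
  expect_error(generate_cohort(tt, 3, seed = 1), "n_subjects")
})

test_that("zero LCD noise yields exactly the 8% target loss", {
  tt <- generate_truth(sim_config(p_genes = 5), seed = 2)
  co <- generate_cohort(tt, 30, seed = 8, lcd_loss_sd = 0,
                        mean_lcd_loss = 0.08)
  w <- reshape(co[, c("subject_id", "cid", "weight")],
               idvar = "subject_id", timevar = "cid", direction = "wide")
  expect_equal(w$weight.2, 0.92 * w$weight.1)
})

test_that("the regain fraction is honoured at the 50%-of-loss rule", {
  tt <- generate_truth(sim_config(p_genes = 5), seed = 2)
  co <- generate_cohort(tt, 400, seed = 11, regain_fraction = 0.5)
  w <- reshape(co[, c("subject_id", "cid", "weight")],
               idvar = "subject_id", timevar = "cid", direction = "wide")
  grp <- assign_weight_change_group(w$weight.1, w$weight.2, w$weight.3)
  # binomial(400, 0.5): allow 4 sigma around 200
  expect_gt(sum(grp == "regain"), 200 - 4 * 10)
  expect_lt(sum(grp == "regain"), 200 + 4 * 10)
  expect_gt(sum(grp == "loss"), 0)
})

test_that("with everything off, expression is exactly the GGM draw", {
  # the same seed consumes the same RNG stream whatever the SDs are, so the
  # noiseless output is the pure GGM draw and turning one component on
  # changes the output by exactly that component
  tt0 <- noiseless(generate_truth(null_config(p = 6), seed = 5))
  co <- generate_cohort(tt0, 10, seed = 5)
  e0 <- generate_expression(tt0, co, seed = 6)
  tt1 <- tt0
  tt1$noise_sd <- 0.3
  e1 <- generate_expression(tt1, co, seed = 6)
  resid <- e1$mat - e0$mat
  expect_gt(sd(resid), 0.25)
  expect_lt(sd(resid), 0.35)
  # and the noiseless version has GGM covariance: diagonal of cov matches
  # the truth marginal variances at large n
  co_big <- generate_cohort(tt0, 400, seed = 7)
  eb <- generate_expression(tt0, co_big, seed = 8)
  m <- eb$mat[, eb$samples$cid == 1 &
                co_big$sex[match(eb$samples$subject_id,
                                 co_big$subject_id)] == "F"]
  sigma <- solve(tt0$precision$F)
  expect_equal(unname(apply(m, 1, var)), unname(diag(sigma)),
               tolerance = 0.25)
})

test_that("injected sex and diet effects appear in sample-mean contrasts", {
  cfg <- null_config(p = 8)
  tt <- noiseless(generate_truth(cfg, seed = 21))
  tt$sex_effect["G001"] <- 1.0
  tt$diet_pattern["G002"] <- "end_down"
  tt$diet_shift["G002"] <- 0.5
  co <- generate_cohort(tt, 500, seed = 22)
  e <- generate_expression(tt, co, seed = 23)
  sex <- co$sex[match(e$samples$subject_id, co$subject_id)]
  d_sex <- mean(e$mat["G001", sex == "F"]) - mean(e$mat["G001", sex == "M"])
  expect_lt(abs(d_sex - 1.0), 0.1)
  d13 <- mean(e$mat["G002", e$samples$cid == 3]) -
    mean(e$mat["G002", e$samples$cid == 1])
  expect_lt(abs(d13 - (-0.5)), 0.1)
})

test_that("large-n GGM draws reproduce the truth covariance", {
  tt <- generate_truth(sim_config(p_genes = 10), seed = 31)
  sigma <- solve(tt$precision$M)
  frob <- function(n) {
    set.seed(41)
    x <- draw_ggm(tt, "M", n)
    norm(cov(x) - sigma, "F")
  }
  errs <- c(frob(100), frob(1000), frob(10000))
  expect_true(all(diff(errs) < 0))
})

test_that("Ct plates carry calibrator structure and missingness", {
  tt <- generate_truth(sim_config(p_genes = 10), seed = 2)
  co <- generate_cohort(tt, 150, seed = 3)
  e <- with_reference(generate_expression(tt, co, seed = 4))
  ct <- generate_ct_plates(e, seed = 5, missing_fraction = 0.05)
  # every plate has calibrator and water wells
  for (pl in unique(ct$plate)) {
    expect_true(any(ct$is_calibrator[ct$plate == pl]))
    expect_true(any(ct$is_water[ct$plate == pl]))
  }
  # missing fraction approximately honoured (>= water wells alone)
  frac <- mean(ct$ct[!ct$is_water] == 999)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  # calibrator raw Ct varies across plates when offsets present, but the
  # delta-Ct of any gene vs the reference is constant (offsets cancel)
  ct0 <- generate_ct_plates(e, seed = 5, well_noise_sd = 0)
  cal <- ct0[ct0$is_calibrator, ]
  g1 <- cal$ct[cal$gene == "G001"]
  expect_gt(sd(g1), 0)
  dct <- g1 - cal$ct[cal$gene == "REF"]
  expect_equal(max(dct) - min(dct), 0)
})

test_that("genotype doses follow Hardy-Weinberg at the configured MAF", {
  tt <- generate_truth(sim_config(p_genes = 2, eqtl_frac = 0), seed = 2)
  co <- generate_cohort(tt, 5000, seed = 3)
  g <- generate_genotypes(tt, co,
                          snp_config(n_per_gene = 1,
                                     maf_range = c(0.5, 0.5),
                                     frac_hwe_violators = 0,
                                     frac_low_call = 0),
                          seed = 4)
  freq <- table(factor(g$doses[1, ], levels = 0:2)) / ncol(g$doses)
  expect_equal(unname(as.vector(freq)), c(0.25, 0.5, 0.25),
               tolerance = 0.05)
  expect_error(
    generate_genotypes(tt, co, snp_config(maf_range = c(0, 0.5)), seed = 1),
    "MAF")
})

test_that("eQTL effects added to expression are recovered by OLS", {
  cfg <- null_config(p = 4)
  tt <- generate_truth(cfg, seed = 51)
  tt$eqtl_beta["G001"] <- 0.5
  co <- generate_cohort(tt, 400, seed = 52)
  e <- generate_expression(tt, co, seed = 53)
  g <- generate_genotypes(tt, co,
                          snp_config(n_per_gene = 1,
                                     maf_range = c(0.3, 0.3),
                                     frac_hwe_violators = 0,
                                     frac_low_call = 0),
                          seed = 54, expr = e)
  e1 <- expr_at_cid(g$expr, 1)
  dose <- g$doses["rs_G001_1", e1$samples$subject_id]
  beta_hat <- coef(lm(e1$mat["G001", ] ~ dose))["dose"]
  expect_lt(abs(beta_hat - 0.5), 0.15)
})
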