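test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03)$q, 0.03)                    # single p
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04))$q, c(0.03, 0.03, 0.04))
  expect_false(any(bh_adjust(rep(1, 5))$reject))
  expect_length(bh_adjust(numeric(0))$q, 0)
  set.seed(7)
  for (m in 1:8) {
    for (r in 1:25) {
      p <- round(runif(m), 3)
      expect_equal(bh_adjust(p)$q, bh_oracle(p), tolerance = 1e-12)
    }
  }
  # q >= p always
  p <- runif(50)
  expect_true(all(bh_adjust(p)$q >= p))
})

test_that("mixed-model estimates match OLS when random variances are zero", {
  tt <- noiseless(generate_truth(null_config(p = 5), seed = 12))
  tt$noise_sd <- 0.5
  tt$sex_effect["G001"] <- 0.8
  # balanced centre x sex design: GLS and OLS fixed effects coincide
  co <- generate_cohort(tt, 80, seed = 13, female_frac = 0.5)
  e <- generate_expression(tt, co, seed = 14)
  ph <- derive_phenotypes(co)
  fits_mm <- fit_gene_lmm(e, ph, design_spec("sex", "centre",
                                             subset = "cid == 1"))
  fits_ls <- fit_gene_lmm(e, ph, design_spec("sex", character(0),
                                             subset = "cid == 1"))
  for (g in c("G001", "G002")) {
    expect_equal(unname(fits_mm$fits[[g]]$coef["sexM"]),
                 unname(fits_ls$fits[[g]]$coef["sexM"]),
                 tolerance = 1e-6)
  }
  # the singular flag is reported, not an error
  expect_true(is.logical(fits_mm$fits$G001$singular))
})

test_that("an injected sex effect is recovered by the screen", {
  cfg <- null_config(p = 6)
  tt <- generate_truth(cfg, seed = 15)
  tt$sex_effect["G001"] <- 1.0
  co <- generate_cohort(tt, 500, seed = 16)
  e <- generate_expression(tt, co, seed = 17)
  ph <- derive_phenotypes(co)
  fits <- fit_gene_lmm(e, ph, design_spec("sex", "centre",
                                          subset = "cid == 1"))
  tt2 <- term_test(fits, "sex")
  # sexM coefficient = male - female = -effect
  est <- -tt2$estimate[tt2$gene == "G001"]
  expect_lt(abs(est - 1.0), 0.25)
  expect_lt(tt2$q[tt2$gene == "G001"], 0.05)
})

test_that("null-gene p-values are uniform", {
  # one replicate cohort, many independent null genes
  tt <- generate_truth(null_config(p = 60), seed = 18)
  co <- generate_cohort(tt, 120, seed = 19)
  e <- generate_expression(tt, co, seed = 20)
  ph <- derive_phenotypes(co)
  fits <- fit_gene_lmm(e, ph, design_spec(c("sex", "mets"), "centre",
                                          subset = "cid == 1"))
  p <- term_test(fits, "sex")$p
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("visit contrasts carry Tukey adjustment and fold changes", {
  cfg <- null_config(p = 6)
  tt <- generate_truth(cfg, seed = 21)
  tt$diet_pattern["G001"] <- "opposite_down_up"
  tt$diet_shift["G001"] <- 0.5
  tt$diet_pattern["G002"] <- "end_down"
  tt$diet_shift["G002"] <- 0.5
  co <- generate_cohort(tt, 300, seed = 22)
  e <- generate_expression(tt, co, seed = 23)
  ph <- derive_phenotypes(co)
  fits <- fit_gene_lmm(e, ph, design_spec("cid", c("centre", "subject")))
  ctr <- cid_contrasts(fits)
  g1 <- ctr[ctr$gene == "G001", ]
  expect_lt(g1$estimate[g1$contrast == "2-1"], 0)
  expect_gt(g1$estimate[g1$contrast == "3-2"], 0)
  expect_lt(g1$q[g1$contrast == "2-1"], 0.05)
  expect_lt(g1$q[g1$contrast == "3-2"], 0.05)
  # Tukey p >= unadjusted two-sided t p
  punadj <- 2 * pt(-abs(ctr$t), 300 * 3 - 3)
  expect_true(all(ctr$p >= punadj - 1e-12))
  # fold change sign agrees with the contrast estimate
  strong <- abs(ctr$estimate) > 0.2
  expect_true(all(sign(log(ctr$median_fc[strong])) ==
                    sign(ctr$estimate[strong])))
  pat <- classify_diet_patterns(ctr)
  expect_equal(pat$label[pat$gene == "G001"], "opposite_down_up")
  expect_equal(pat$label[pat$gene == "G002"], "end_down")
})

test_that("a two-level factor reduces Tukey to the plain t contrast", {
  # ptukey with 2 means equals the two-sided t distribution
  tvals <- c(0.5, 1.3, 2.1, 3.0)
  for (tv in tvals) {
    expect_equal(ptukey(sqrt(2) * tv, 2, 50, lower.tail = FALSE),
                 2 * pt(-tv, 50), tolerance = 1e-4)
  }
})

test_that("diet-pattern rules apply to synthetic contrast tables", {
  mk <- function(e21, q21, e32, q32, e31, q31) {
    data.frame(gene = "g", contrast = c("2-1", "3-2", "3-1"),
               estimate = c(e21, e32, e31), se = 0.1, t = 0,
               p = c(q21, q32, q31), median_fc = 1,
               q = c(q21, q32, q31))
  }
  expect_equal(classify_diet_patterns(mk(-1, 0.01, 1, 0.01, 0, 0.9))$label,
               "opposite_down_up")
  expect_equal(classify_diet_patterns(mk(1, 0.01, -1, 0.01, 0, 0.9))$label,
               "opposite_up_down")
  expect_equal(classify_diet_patterns(mk(0, 0.9, 0, 0.9, -1, 0.01))$label,
               "end_down")
  expect_equal(classify_diet_patterns(mk(0, 0.9, 0, 0.9, 0, 0.9))$label,
               "null")
  expect_error(classify_diet_patterns(mk(0, 1, 0, 1, 0, 1)[1:2, ]),
               "three")
})

test_that("persistence is plain set intersection", {
  expect_equal(persistent_signature(list(c("A", "B"), c("A", "B"))),
               c("A", "B"))
  expect_equal(persistent_signature(list("A", "B")), character(0))
  expect_equal(
    persistent_signature(list(c("A", "B", "C"), c("B", "C"),
                              c("B", "C", "D"))),
    c("B", "C"))
  expect_error(persistent_signature(list("A")), "2")
})

test_that("covariate robustness keeps only doubly-significant genes", {
  cfg <- null_config(p = 8)
  tt <- generate_truth(cfg, seed = 24)
  tt$sex_effect["G001"] <- 1.2   # genuine, fat-mass-orthogonal effect
  co <- generate_cohort(tt, 300, seed = 25)
  e <- generate_expression(tt, co, seed = 26)
  # G002's sex difference fully mediated by fat mass (fat mass differs by
  # sex; couple expression to it directly)
  ph <- derive_phenotypes(co)
  key <- sample_key(ph$subject_id, ph$cid)
  e$mat["G002", ] <- e$mat["G002", ] +
    0.2 * ph$fat_mass[match(e$samples$column_id, key)]
  f0 <- fit_gene_lmm(e, ph, design_spec("sex", "centre",
                                        subset = "cid == 1"))
  f1 <- fit_gene_lmm(e, ph, design_spec(c("sex", "fat_mass"), "centre",
                                        subset = "cid == 1"))
  rob <- covariate_robustness(f0, f1, "sex")
  expect_true(rob$robust[rob$gene == "G001"])
  expect_false(rob$robust[rob$gene == "G002"])
  expect_false(rob$robust[rob$gene == "G003"])  # null gene
  f_sub <- f0
  f_sub$genes <- f_sub$genes[-1]
  expect_error(covariate_robustness(f_sub, f1, "sex"), "different gene")
})

test_that("BMI screen recovers slopes and reports decile ratios", {
  cfg <- null_config(p = 5)
  tt <- generate_truth(cfg, seed = 27)
  tt$bmi_slope["G001"] <- 0.1
  co <- generate_cohort(tt, 400, seed = 28)
  e <- generate_expression(tt, co, seed = 29)
  ph <- derive_phenotypes(co)
  sc <- bmi_dependency_screen(e, ph, sex = "F")
  expect_true("G001" %in% sc$persistent)
  est <- sc$table$estimate[sc$table$gene == "G001"]
  expect_true(all(abs(est - 0.1) < 0.05))
  # constant-expression gene has decile ratio ~1 and no signal
  expect_false("G002" %in% sc$persistent)
  r2 <- sc$table$decile_ratio[sc$table$gene == "G002"]
  expect_true(all(r2 > 0.5 & r2 < 2))
})

test_that("weight-group markers detect a regain-specific shift", {
  cfg <- null_config(p = 5)
  tt <- generate_truth(cfg, seed = 30)
  co <- generate_cohort(tt, 200, seed = 31)
  e <- generate_expression(tt, co, seed = 32)
  ph <- derive_phenotypes(co)
  # inject +0.6 log2 CID3-CID2 shift in regain women for G001
  regain <- unique(ph$subject_id[ph$weight_change_group == "regain" &
                                   ph$sex == "F"])
  cols <- sample_key(regain, 3)
  cols <- cols[cols %in% e$samples$column_id]
  e$mat["G001", cols] <- e$mat["G001", cols] + 0.6
  mk <- weight_group_markers(e, ph, sex = "F")
  expect_lt(mk$q[mk$gene == "G001"], 0.05)
  expect_gt(mk$ratio[mk$gene == "G001"], 1.3)
  # null genes: ratio near 1
  expect_true(all(abs(log2(mk$ratio[mk$gene != "G001"])) < 0.5))
})
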