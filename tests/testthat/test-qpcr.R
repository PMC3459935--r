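make_ct_fixture <- function(p = 10, n_subjects = 150, seed = 2,
                            ...) {
  tt <- generate_truth(sim_config(p_genes = p), seed = seed)
  co <- generate_cohort(tt, n_subjects, seed = seed + 1)
  e <- with_reference(generate_expression(tt, co, seed = seed + 2))
  list(truth = tt, cohort = co, expr = e,
       ct = generate_ct_plates(e, seed = seed + 3, ...))
}

test_that("gene QC removes absent, high-Ct and calibrator-outlier genes", {
  fx <- make_ct_fixture(high_ct_genes = "G002")
  ct <- fx$ct
  # force one gene fully absent
  ct$ct[ct$gene == "G001"] <- 999
  qc <- qc_filter_genes(ct)
  expect_true(all(c("G001", "G002") %in% qc$report$gene))
  expect_equal(qc$report$reason[qc$report$gene == "G001"], "absent")
  expect_false(any(c("G001", "G002") %in% qc$ct$gene))
  # stable genes retained
  expect_true("G003" %in% qc$ct$gene)
})

test_that("calibrator outlier rule uses the median/MAD count", {
  # 50 plates; one gene displaced by +5 Ct on 11 plates (22% > 20%)
  genes <- c("GA", "GB")
  plates <- 1:50
  rows <- expand.grid(plate = plates, gene = genes)
  ct <- data.frame(plate = rows$plate, set = "A", well = 1,
                   sample_id = "CAL", cid = NA, gene = rows$gene,
                   ct = 20, is_calibrator = TRUE, is_water = FALSE)
  # one endogenous well per gene so the absent rule has data
  endo <- data.frame(plate = 1, set = "A", well = 2, sample_id = "S1",
                     cid = 1, gene = genes, ct = 22,
                     is_calibrator = FALSE, is_water = FALSE)
  ct$ct[ct$gene == "GA" & ct$plate <= 11] <- 25
  qc <- qc_filter_genes(rbind(ct, endo))
  expect_equal(qc$report$gene, "GA")
  expect_equal(qc$report$reason, "calibrator_outliers")
  # 10 plates displaced = 20%, not > 20%: retained
  ct$ct[ct$gene == "GA"] <- 20
  ct$ct[ct$gene == "GA" & ct$plate <= 10] <- 25
  qc2 <- qc_filter_genes(rbind(ct, endo))
  expect_equal(nrow(qc2$report), 0)
})

test_that("delta-Ct follows the 2^-dCt formula and shift invariance", {
  ct <- data.frame(plate = rep(1:2, each = 3), set = "A", well = 1:3,
                   sample_id = rep(c("S1", "S2"), each = 3), cid = 1,
                   gene = rep(c("REF", "GA", "GB"), 2),
                   ct = c(20, 20, 25, 20, 22, 18),
                   is_calibrator = FALSE, is_water = FALSE)
  e <- delta_ct_normalize(ct, "REF")
  expect_equal(e$mat["GA", "S1_1"], 0)           # Ct equal -> log2 0
  expect_equal(e$mat["GB", "S1_1"], -5)          # 25 vs 20 -> 2^-5
  expect_equal(2^e$mat["GB", "S1_1"], 0.03125)
  # +2 Ct on one whole plate leaves dCt unchanged
  ct2 <- ct
  ct2$ct[ct2$plate == 2] <- ct2$ct[ct2$plate == 2] + 2
  e2 <- delta_ct_normalize(ct2, "REF")
  expect_equal(e2$mat, e$mat)
  # sentinel propagates; missing reference blanks the sample
  ct3 <- ct
  ct3$ct[ct3$gene == "REF" & ct3$sample_id == "S2"] <- 999
  e3 <- delta_ct_normalize(ct3, "REF")
  expect_true(all(is.na(e3$mat[, "S2_1"])))
  expect_false(anyNA(e3$mat[, "S1_1"]))
})

test_that("zero-noise Ct generation round-trips through delta-Ct", {
  tt <- noiseless(generate_truth(null_config(p = 8), seed = 5))
  co <- generate_cohort(tt, 20, seed = 6)
  e <- with_reference(generate_expression(tt, co, seed = 7))
  ct <- generate_ct_plates(e, seed = 8, plate_offset_sd = 0,
                           well_noise_sd = 0)
  back <- delta_ct_normalize(ct, "REF")
  expect_equal(back$mat[rownames(e$mat), e$samples$column_id], e$mat)
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(c(1, 2, 3), c(4, 5, 6))
  q <- quantile_normalize(m)
  expect_equal(q[, 1], c(2.5, 3.5, 4.5))
  expect_equal(q[, 2], c(2.5, 3.5, 4.5))
  # identical columns unchanged
  m2 <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(quantile_normalize(m2), m2)
  # idempotence and exact multiset equality on random input
  set.seed(1)
  m3 <- matrix(rnorm(60), 12, 5)
  q3 <- quantile_normalize(m3)
  expect_equal(quantile_normalize(q3), q3)
  for (j in 2:5) expect_equal(sort(q3[, j]), sort(q3[, 1]))
  expect_error(quantile_normalize(cbind(c(NA, NA), c(1, 2))), "missing")
})

test_that("rank-invariant normalization honours its contracts", {
  set.seed(2)
  ref <- sort(rnorm(20, sd = 3))
  m <- cbind(a = ref, b = ref + 2)
  out <- rank_invariant_normalize(m, reference_profile = ref)
  expect_equal(out[, "a"], ref, tolerance = 1e-8)        # identity
  expect_equal(out[, "b"], ref, tolerance = 1e-6)        # shift removed
  # permuted ranks -> refused
  m2 <- cbind(ref, rev(ref))
  expect_error(rank_invariant_normalize(m2, reference_profile = ref),
               "rank-invariant set too small")
})

test_that("geNorm stability matches the brute-force pairwise-SD oracle", {
  set.seed(3)
  m <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("g", 1:5), NULL))
  mm <- genorm_m(m)
  # double loop oracle
  oracle <- sapply(1:5, function(j) {
    mean(sapply(setdiff(1:5, j), function(k) sd(m[j, ] - m[k, ])))
  })
  expect_equal(unname(mm), oracle, tolerance = 1e-12)
  # constant-offset pair has V = 0
  m2 <- rbind(g1 = m[1, ], g2 = m[1, ] + 3, g3 = rnorm(10))
  expect_equal(sd(m2["g1", ] - m2["g2", ]), 0)
  # a noisy candidate is dropped first
  m3 <- rbind(stable1 = m[1, ], stable2 = m[1, ] + 1,
              noisy = m[1, ] + rnorm(10, sd = 1))
  rk <- genorm_rank(m3)
  expect_equal(rk$gene[rk$rank == 3], "noisy")
  expect_equal(max(rk$M), rk$M[rk$gene == "noisy"])
})

test_that("calibrator CV singles out the stable-reference delta-Ct method", {
  fx <- make_ct_fixture(p = 40)
  # identical calibrator everywhere -> CV 0 for every method
  ct0 <- generate_ct_plates(fx$expr, seed = 9, plate_offset_sd = 0,
                            well_noise_sd = 0)
  cv0 <- calibrator_cv(ct0, methods = c("raw", "dct"),
                       reference_gene = "REF")
  expect_equal(cv0$cv, c(0, 0), tolerance = 1e-12)
  # plate offsets, no well noise: dCt cancels them exactly, raw does not
  ct1 <- generate_ct_plates(fx$expr, seed = 10, well_noise_sd = 0)
  cv1 <- calibrator_cv(ct1, methods = c("raw", "dct"),
                       reference_gene = "REF")
  expect_equal(cv1$cv[cv1$method == "dct"], 0, tolerance = 1e-12)
  expect_gt(cv1$cv[cv1$method == "raw"], 0.05)
  # default scenario: reference-gene dCt beats raw and quantile, stably
  for (s in 1:3) {
    ct2 <- generate_ct_plates(fx$expr, seed = 100 + s)
    cv2 <- calibrator_cv(ct2, methods = c("raw", "dct", "quantile"),
                         reference_gene = "REF")
    expect_lt(cv2$cv[cv2$method == "dct"], cv2$cv[cv2$method == "raw"])
    expect_lt(cv2$cv[cv2$method == "dct"],
              cv2$cv[cv2$method == "quantile"])
  }
  expect_error(calibrator_cv(fx$ct, methods = "loess"), "unknown method")
})

test_that("kNN imputation fills from nearest genes", {
  set.seed(4)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  expect_identical(knn_impute(m), m)  # nothing to do
  # exact duplicate with one masked entry imputes the duplicate's value
  m2 <- rbind(m, dup = m[1, ])
  m2["dup", 3] <- NA
  expect_equal(knn_impute(m2, k = 3)["dup", 3], m[1, 3])
  # masking experiment: RMSE not worse at k = 10 than k = 1 under noise
  set.seed(5)
  base <- matrix(rnorm(40 * 30), 40, 30)
  noisy <- base + matrix(rnorm(40 * 30, sd = 0.3), 40, 30)
  rownames(noisy) <- paste0("g", 1:40)
  mask <- cbind(sample(1:40, 25, replace = TRUE), sample(1:30, 25,
                                                         replace = TRUE))
  mask <- mask[!duplicated(mask), ]
  masked <- noisy
  masked[mask] <- NA
  rmse <- sapply(c(1, 10), function(k) {
    imp <- knn_impute(masked, k = k)
    sqrt(mean((imp[mask] - noisy[mask])^2))
  })
  expect_lte(rmse[2], rmse[1])
  # gene missing everywhere is refused
  bad <- noisy
  bad[1, ] <- NA
  expect_error(knn_impute(bad), "missing everywhere")
})
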