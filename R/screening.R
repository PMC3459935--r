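#' Design specification for a gene-by-gene mixed-model screen
#'
#' Describes the model fitted to every gene's log2 expression: ordered fixed
#' terms (cohort columns; \code{cid} and categorical terms are handled as
#' factors), random intercepts (\code{centre} and/or \code{subject};
#' \code{subject} only makes sense with repeated measures), an optional
#' subset filter on the phenotype rows, and covariates to log-transform
#' (for skewed clinical variables).
#'
#' @param fixed character vector of fixed-effect terms.
#' @param random subset of \code{c("centre", "subject")}.
#' @param subset optional filter expressed as a string evaluated in the
#'   phenotype table, e.g. \code{'sex == "F"'}.
#' @param log_terms covariates to replace by \code{log(x)}.
#' @param name optional label.
#' @return list of class \code{design_spec}.
#' @export
design_spec <- function(fixed, random = c("centre", "subject"),
                        subset = NULL, log_terms = character(),
                        name = NULL) {
  stopifnot(length(fixed) >= 1, all(random %in% c("centre", "subject")))
  structure(list(fixed = fixed, random = random, subset = subset,
                 log_terms = log_terms, name = name),
            class = "design_spec")
}

#' Preconfigured screening designs
#'
#' Named design specifications mirroring the study's screens: diet-phase
#' regulation with and without weight (\code{opposite},
#' \code{opposite_weight}), end-of-intervention regulation (\code{end}),
#' weight-change markers (\code{weight_group}), sexual dimorphism without
#' and with fat mass (\code{sex}, \code{sex_fatmass}), metabolic-syndrome
#' contrast (\code{mets}), and the women-only BMI screen (\code{bmi}).
#'
#' @return named list of [design_spec()] objects.
#' @export
design_presets <- function() {
  list(
    opposite = design_spec(c("cid"), c("centre", "subject"),
                           name = "diet-phase contrasts"),
    opposite_weight = design_spec(c("cid", "weight"),
                                  c("centre", "subject"),
                                  name = "diet-phase contrasts + weight"),
    end = design_spec(c("weight", "cid", "diet"), c("centre", "subject"),
                      name = "end-of-intervention"),
    sex = design_spec("sex", "centre", name = "sexual dimorphism"),
    sex_fatmass = design_spec(c("sex", "fat_mass"), "centre",
                              name = "sexual dimorphism + fat mass"),
    mets = design_spec(c("sex", "mets"), "centre",
                       name = "metabolic syndrome"),
    bmi = design_spec("bmi", "centre", subset = 'sex == "F"',
                      name = "BMI dependency (women)")
  )
}

# Near-zero random-effect variances routinely trip lme4's gradient/Hessian
# heuristics on screens over many genes; degenerate fits are caught through
# the singular flag and the coefficient-covariance check instead.
screen_lmer_control <- function() {
  lme4::lmerControl(check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore")
}

# refit() does not honour the control's check switches; muffle only the
# convergence-diagnostic warnings, let everything else through.
quiet_convergence <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("failed to converge|scaled gradient|degenerate",
              conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Join expression columns to phenotype rows and build the model frame.
assemble_design <- function(expr, pheno, spec) {
  ran_cols <- ifelse(spec$random == "subject", "subject_id", spec$random)
  sub_vars <- if (is.null(spec$subset)) character() else
    intersect(all.vars(parse(text = spec$subset)), colnames(pheno))
  need <- unique(c(spec$fixed, ran_cols, sub_vars, "subject_id", "cid"))
  miss <- setdiff(need, c(colnames(pheno), "subject_id", "cid"))
  if (length(miss)) stop("terms absent from phenotype table: ",
                         paste(miss, collapse = ", "))
  key_p <- sample_key(pheno$subject_id, pheno$cid)
  keep <- expr$samples$column_id %in% key_p
  s <- expr$samples[keep, , drop = FALSE]
  fr <- pheno[match(s$column_id, key_p), need, drop = FALSE]
  fr$subject_id <- s$subject_id
  if (!is.null(spec$subset)) {
    sel <- eval(parse(text = spec$subset), fr, parent.frame())
    fr <- fr[sel, , drop = FALSE]
    s <- s[sel, , drop = FALSE]
  }
  for (v in intersect(spec$log_terms, colnames(fr))) fr[[v]] <- log(fr[[v]])
  for (v in intersect(c("cid", "sex", "diet", "centre", "mets", "group",
                        "weight_change_group"), colnames(fr))) {
    fr[[v]] <- factor(fr[[v]])
  }
  fr$subject_id <- factor(fr$subject_id)
  cc <- stats::complete.cases(fr[, unique(c(spec$fixed, ran_cols)),
                                 drop = FALSE])
  list(frame = droplevels(fr[cc, , drop = FALSE]),
       ymat = t(expr$mat[, s$column_id[cc], drop = FALSE]))
}

fixed_formula <- function(spec, lhs = "..y..") {
  rhs <- paste(spec$fixed, collapse = " + ")
  ran <- vapply(spec$random,
                function(r) paste0("(1 | ",
                                   if (r == "subject") "subject_id" else r,
                                   ")"), "")
  if (length(ran)) rhs <- paste(rhs, paste(ran, collapse = " + "),
                                sep = " + ")
  stats::as.formula(paste(lhs, "~", rhs))
}

extract_fit <- function(fm, n) {
  if (inherits(fm, "merMod")) {
    b <- lme4::fixef(fm)
    v <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fm))),
                  error = function(e) NULL)
    if (is.null(v) || anyNA(v)) {
      return(list(ok = FALSE, n = n,
                  reason = "degenerate coefficient covariance"))
    }
    dimnames(v) <- list(names(b), names(b))
    list(coef = b, vcov = v, df = n - length(b),
         singular = lme4::isSingular(fm), n = n, ok = TRUE)
  } else {
    b <- stats::coef(fm)
    list(coef = b, vcov = stats::vcov(fm), df = fm$df.residual,
         singular = FALSE, n = n, ok = TRUE)
  }
}

#' Fit the screening mixed model to every gene
#'
#' Fits the design's linear mixed model (REML via \code{lme4}, or ordinary
#' least squares when no random term is requested) to each gene's log2
#' expression. Random-effect variances estimated at zero are reported with
#' a \code{singular} flag, not as failures; genes with a rank-deficient
#' fixed design are flagged and excluded from downstream summaries with a
#' reason. Inference downstream is by Wald tests with residual-based
#' degrees of freedom (\code{n - p}).
#'
#' @param expr an \code{expr_set}.
#' @param pheno phenotype table with one row per (subject, cid), typically
#'   [derive_phenotypes()] output.
#' @param spec a [design_spec()].
#' @return object of class \code{gene_fits}: per-gene coefficient vectors,
#'   covariance matrices, residual df and flags, plus the shared model
#'   frame.
#' @export
fit_gene_lmm <- function(expr, pheno, spec) {
  ad <- assemble_design(expr, pheno, spec)
  fr <- ad$frame
  if (length(spec$random)) {
    for (r in spec$random) {
      v <- if (r == "subject") "subject_id" else r
      if (nlevels(factor(fr[[v]])) < 2) {
        stop("random grouping '", r, "' has fewer than 2 levels")
      }
    }
  }
  genes <- colnames(ad$ymat)
  n <- nrow(fr)
  form <- fixed_formula(spec)
  fits <- vector("list", length(genes))
  names(fits) <- genes

  if (!length(spec$random)) {
    x <- stats::model.matrix(stats::reformulate(spec$fixed), fr)
    qrx <- qr(x)
    if (qrx$rank < ncol(x)) stop("rank-deficient fixed design")
    xtx_inv <- chol2inv(qr.R(qrx))
    dimnames(xtx_inv) <- list(colnames(x), colnames(x))
    for (g in genes) {
      y <- ad$ymat[, g]
      b <- qr.coef(qrx, y)
      res <- y - drop(x %*% b)
      s2 <- sum(res^2) / (n - ncol(x))
      fits[[g]] <- list(coef = b, vcov = s2 * xtx_inv, df = n - ncol(x),
                        singular = FALSE, n = n, ok = TRUE)
    }
  } else {
    fr$..y.. <- ad$ymat[, 1]
    base <- tryCatch(
      suppressMessages(lme4::lmer(form, data = fr, REML = TRUE,
                                  control = screen_lmer_control())),
      error = function(e) e)
    if (inherits(base, "error")) stop("base model failed: ",
                                      conditionMessage(base))
    for (g in genes) {
      y <- ad$ymat[, g]
      fm <- tryCatch(quiet_convergence({
        if (anyNA(y)) {
          fr2 <- fr
          fr2$..y.. <- y
          suppressMessages(lme4::lmer(form, data = fr2[!is.na(y), ],
                                      REML = TRUE,
                                      control = screen_lmer_control()))
        } else {
          suppressMessages(lme4::refit(base, newresp = y))
        }
      }), error = function(e) e)
      fits[[g]] <- if (inherits(fm, "error")) {
        list(ok = FALSE, reason = conditionMessage(fm), n = sum(!is.na(y)))
      } else {
        extract_fit(fm, sum(!is.na(y)))
      }
    }
  }
  structure(list(fits = fits, genes = genes, frame = fr, ymat = ad$ymat,
                 spec = spec, formula = form),
            class = "gene_fits")
}

#' @export
print.gene_fits <- function(x, ...) {
  cat("gene_fits:", length(x$genes), "genes;",
      sum(vapply(x$fits, function(f) isTRUE(f$ok), TRUE)), "fitted;",
      "model:", deparse(x$formula), "\n")
  invisible(x)
}

#' Per-gene Wald test for one model term
#'
#' Extracts the coefficient of a single-df fixed term (e.g. \code{sex},
#' \code{bmi}, a two-level group) from every gene's fit and computes a Wald
#' t test on residual degrees of freedom, with BH q-values across genes.
#'
#' @param fits a \code{gene_fits}.
#' @param term model term; for a factor, its non-reference coefficient name
#'   (e.g. \code{"sexM"}) or the bare term name if unambiguous.
#' @return data.frame \code{gene}, \code{estimate}, \code{se}, \code{t},
#'   \code{p}, \code{q}.
#' @export
term_test <- function(fits, term) {
  rows <- lapply(fits$genes, function(g) {
    f <- fits$fits[[g]]
    if (!isTRUE(f$ok)) {
      return(data.frame(gene = g, estimate = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_))
    }
    nm <- names(f$coef)
    j <- if (term %in% nm) term else nm[startsWith(nm, term)]
    if (length(j) != 1) stop("term '", term, "' does not identify one ",
                             "coefficient; candidates: ",
                             paste(nm, collapse = ", "))
    est <- unname(f$coef[j])
    se <- sqrt(f$vcov[j, j])
    tt <- est / se
    data.frame(gene = g, estimate = est, se = se, t = tt,
               p = 2 * stats::pt(-abs(tt), f$df))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)$q
  out
}

#' Pairwise visit contrasts with Tukey adjustment
#'
#' Computes all pairwise contrasts between clinical-investigation-day (CID)
#' means from each gene's fitted model, with family-wise adjustment from
#' the studentized-range distribution (Tukey HSD) on model-based standard
#' errors and residual degrees of freedom, BH q-values across genes per
#' contrast, and the median across subjects of the per-subject fold change
#' between the two visits.
#'
#' @param fits a \code{gene_fits} whose design includes \code{cid}.
#' @return data.frame \code{gene}, \code{contrast} (\code{"2-1"},
#'   \code{"3-2"}, \code{"3-1"}), \code{estimate} (log2), \code{se},
#'   \code{t}, \code{p} (Tukey-adjusted), \code{q}, \code{median_fc}.
#' @export
cid_contrasts <- function(fits) {
  if (!"cid" %in% fits$spec$fixed) stop("cid is not in the fixed terms")
  lv <- levels(fits$frame$cid)
  k <- length(lv)
  prs <- utils::combn(k, 2)
  coef_name <- function(l) paste0("cid", l)

  med_fc <- function(g, a, b) {
    fr <- fits$frame
    y <- fits$ymat[, g]
    ya <- y[fr$cid == a]
    names(ya) <- as.character(fr$subject_id[fr$cid == a])
    yb <- y[fr$cid == b]
    names(yb) <- as.character(fr$subject_id[fr$cid == b])
    common <- intersect(names(ya), names(yb))
    if (!length(common)) return(NA_real_)
    stats::median(2^(yb[common] - ya[common]), na.rm = TRUE)
  }

  rows <- list()
  for (g in fits$genes) {
    f <- fits$fits[[g]]
    if (!isTRUE(f$ok)) next
    for (ci in seq_len(ncol(prs))) {
      a <- lv[prs[1, ci]]
      b <- lv[prs[2, ci]]
      l <- stats::setNames(numeric(length(f$coef)), names(f$coef))
      if (coef_name(b) %in% names(l)) l[coef_name(b)] <- 1
      if (coef_name(a) %in% names(l)) l[coef_name(a)] <- -1
      est <- sum(l * f$coef)
      se <- sqrt(drop(t(l) %*% f$vcov %*% l))
      tt <- est / se
      p <- stats::ptukey(sqrt(2) * abs(tt), nmeans = k, df = f$df,
                         lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, contrast = paste0(b, "-", a), estimate = est, se = se,
        t = tt, p = p, median_fc = med_fc(g, a, b),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (ctr in unique(out$contrast)) {
    i <- out$contrast == ctr
    out$q[i] <- bh_adjust(out$p[i])$q
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity and rejection flags
#' at the chosen FDR level.
#'
#' @param pvalues numeric vector in \code{[0, 1]} (NAs allowed).
#' @param alpha FDR level.
#' @return list with \code{q} (adjusted values) and \code{reject}
#'   (\code{q <= alpha}).
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(list(q = numeric(0), reject = logical(0)))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Classify diet-regulation patterns from visit contrasts
#'
#' A gene is oppositely regulated when the baseline-to-LCD and LCD-to-WMD
#' contrasts are both significant with opposite signs
#' (\code{opposite_down_up} when expression first falls), and
#' end-regulated when the baseline-to-WMD contrast is significant
#' (\code{end_down}/\code{end_up} by sign). The two labels are recorded
#' side by side, not exclusively; \code{label} gives a single summary
#' (opposite wins over end; otherwise \code{"null"}).
#'
#' @param contrasts output of [cid_contrasts()] with contrasts
#'   \code{"2-1"}, \code{"3-2"}, \code{"3-1"}.
#' @param alpha FDR level applied to the q-values.
#' @return data.frame \code{gene}, \code{opposite}, \code{end},
#'   \code{label}.
#' @export
classify_diet_patterns <- function(contrasts, alpha = 0.05) {
  need <- c("2-1", "3-2", "3-1")
  if (!all(need %in% contrasts$contrast)) {
    stop("all three visit contrasts are required")
  }
  wide <- function(ctr, col) {
    d <- contrasts[contrasts$contrast == ctr, ]
    stats::setNames(d[[col]], d$gene)
  }
  genes <- unique(contrasts$gene)
  e21 <- wide("2-1", "estimate")[genes]
  e32 <- wide("3-2", "estimate")[genes]
  e31 <- wide("3-1", "estimate")[genes]
  s21 <- wide("2-1", "q")[genes] <= alpha
  s32 <- wide("3-2", "q")[genes] <= alpha
  s31 <- wide("3-1", "q")[genes] <= alpha
  opp <- ifelse(s21 & s32 & (sign(e21) * sign(e32) < 0),
                ifelse(e21 < 0, "opposite_down_up", "opposite_up_down"),
                "none")
  end <- ifelse(s31, ifelse(e31 < 0, "end_down", "end_up"), "none")
  label <- ifelse(opp != "none", opp, ifelse(end != "none", end, "null"))
  data.frame(gene = genes, opposite = opp, end = end, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Covariate robustness of a focal effect
#'
#' Flags genes whose focal term stays BH-significant after a covariate
#' (e.g. weight or fat mass) is added to the model — the
#' "covariate-independent" genes.
#'
#' @param fit_without,fit_with \code{gene_fits} from designs differing only
#'   by the covariate.
#' @param term focal term (see [term_test()]).
#' @param alpha FDR level.
#' @return data.frame \code{gene}, \code{q_without}, \code{q_with},
#'   \code{robust}.
#' @export
covariate_robustness <- function(fit_without, fit_with, term,
                                 alpha = 0.05) {
  if (!identical(sort(fit_without$genes), sort(fit_with$genes))) {
    stop("the two fits cover different gene sets")
  }
  a <- term_test(fit_without, term)
  b <- term_test(fit_with, term)
  b <- b[match(a$gene, b$gene), ]
  data.frame(gene = a$gene, q_without = a$q, q_with = b$q,
             robust = !is.na(a$q) & !is.na(b$q) &
                      a$q <= alpha & b$q <= alpha,
             stringsAsFactors = FALSE)
}

#' Genes significant in every result set
#'
#' @param sets list (length >= 2) of gene-id vectors, e.g. the significant
#'   sets at each dietary phase.
#' @return their intersection.
#' @export
persistent_signature <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  Reduce(intersect, sets)
}

#' BMI-dependency screen across the dietary intervention
#'
#' Per visit, fits each gene's log2 expression on BMI with a centre random
#' intercept (adding diet arm as a fixed term at the weight-maintenance
#' visit), applies BH within visit, and keeps the genes significant at
#' every visit. The reporting ratio divides the mean linear expression of
#' the top BMI decile by the bottom decile; deciles with fewer than 2
#' subjects flag the ratio unavailable.
#'
#' @param expr an \code{expr_set} covering all visits.
#' @param pheno derived phenotype table.
#' @param sex which sex stratum to screen.
#' @param alpha FDR level.
#' @return list with \code{persistent} (gene ids) and \code{table}
#'   (per gene x cid: \code{estimate}, \code{p}, \code{q},
#'   \code{decile_ratio}).
#' @export
bmi_dependency_screen <- function(expr, pheno, sex = "F", alpha = 0.05) {
  out <- list()
  for (cid in sort(unique(pheno$cid))) {
    fixed <- if (cid == 3) c("bmi", "diet") else "bmi"
    spec <- design_spec(fixed, "centre",
                        subset = sprintf('sex == "%s" & cid == %d',
                                         sex, cid))
    fits <- fit_gene_lmm(expr, pheno, spec)
    tt <- term_test(fits, "bmi")
    fr <- fits$frame
    dec <- stats::quantile(fr$bmi, c(0.1, 0.9))
    lo <- fr$bmi <= dec[1]
    hi <- fr$bmi >= dec[2]
    ratio <- vapply(fits$genes, function(g) {
      if (sum(lo) < 2 || sum(hi) < 2) return(NA_real_)
      mean(2^fits$ymat[hi, g]) / mean(2^fits$ymat[lo, g])
    }, 0)
    tt$cid <- cid
    tt$decile_ratio <- ratio[tt$gene]
    out[[as.character(cid)]] <- tt
  }
  tab <- do.call(rbind, out)
  sig <- lapply(out, function(d) d$gene[!is.na(d$q) & d$q <= alpha])
  list(persistent = persistent_signature(sig), table = tab)
}

#' Markers of weight regain versus continued loss
#'
#' Models each gene's within-subject log2 expression change over the
#' weight-maintenance phase (CID3 - CID2) on the weight-change group
#' (regain vs loss), with CID2 weight and diet arm as fixed covariates and
#' a centre random intercept, and reports the BH-adjusted group effect and
#' the ratio of mean linear fold changes (regain / loss).
#'
#' @param expr an \code{expr_set} covering CID2 and CID3.
#' @param pheno derived phenotype table (needs
#'   \code{weight_change_group}).
#' @param sex optional sex stratum (default women, matching the study
#'   design); \code{NULL} for both.
#' @param alpha FDR level.
#' @return data.frame \code{gene}, \code{estimate}, \code{se}, \code{p},
#'   \code{q}, \code{ratio} (regain over loss mean fold change).
#' @export
weight_group_markers <- function(expr, pheno, sex = "F", alpha = 0.05) {
  ph <- pheno[pheno$weight_change_group %in% c("regain", "loss"), ]
  if (!is.null(sex)) ph <- ph[ph$sex == sex, ]
  subj <- unique(ph$subject_id)
  grp <- ph$weight_change_group[match(subj, ph$subject_id)]
  if (!any(grp == "regain") || !any(grp == "loss")) {
    stop("both weight-change groups must be non-empty")
  }
  k2 <- sample_key(subj, 2)
  k3 <- sample_key(subj, 3)
  ok <- k2 %in% expr$samples$column_id & k3 %in% expr$samples$column_id
  subj <- subj[ok]
  grp <- grp[ok]
  dy <- t(expr$mat[, sample_key(subj, 3), drop = FALSE] -
            expr$mat[, sample_key(subj, 2), drop = FALSE])
  rownames(dy) <- subj
  ph2 <- ph[ph$cid == 2, ]
  ph2 <- ph2[match(subj, ph2$subject_id), ]
  fr <- data.frame(group = factor(grp, levels = c("loss", "regain")),
                   weight = ph2$weight, diet = factor(ph2$diet),
                   centre = factor(ph2$centre))
  dexpr <- expr_set(t(dy),
                    data.frame(column_id = subj, subject_id = subj,
                               cid = NA_integer_,
                               stringsAsFactors = FALSE),
                    method = "log2_ratio_cid3_cid2")
  fr_ph <- cbind(subject_id = subj, cid = NA_integer_, fr)
  # reuse the generic fitter through a one-visit design on the change score
  spec <- design_spec(c("group", "weight", "diet"), "centre")
  ad_expr <- dexpr
  ad_expr$samples$column_id <- subj
  pheno_cs <- fr_ph
  pheno_cs$cid <- 1L
  ad_expr$samples$cid <- 1L
  ad_expr$samples$column_id <- sample_key(subj, 1)
  colnames(ad_expr$mat) <- ad_expr$samples$column_id
  fits <- fit_gene_lmm(ad_expr, pheno_cs, spec)
  tt <- term_test(fits, "groupregain")
  ratio <- vapply(colnames(dy), function(g) {
    mean(2^dy[grp == "regain", g]) / mean(2^dy[grp == "loss", g])
  }, 0)
  tt$ratio <- ratio[tt$gene]
  tt
}
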