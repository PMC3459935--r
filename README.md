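# dietexpr

Adipose tissue is a primary target of dietary weight-loss interventions,
and qPCR panels of a few hundred adipose transcripts measured repeatedly
over an intervention — baseline, the end of a low-calorie diet (LCD), the
end of a weight-maintenance diet (WMD) — are a standard design for asking
which genes respond to diet phases, sex, adiposity, the metabolic
syndrome, and local genetic variation. `dietexpr` is an R package for
analysts of such trials. It implements the complete analysis path as
tested, reusable functions, and ships a synthetic cohort generator that
reproduces the statistical structure of a three-visit multi-centre trial
together with ground truth, so every stage can be validated by parameter
recovery and error-rate simulation.

## What it computes

* **qPCR quantification** — plate QC (high-Ct/absent-gene and
  calibrator-outlier filters), normalization by
  2<sup>−ΔCt</sup> against a reference gene, quantile and rank-invariant
  alternatives, geNorm reference-gene stability ranking
  (M<sub>j</sub> = mean<sub>k</sub> sd<sub>s</sub>(log₂ x<sub>j</sub> −
  log₂ x<sub>k</sub>)), calibrator-CV method comparison, and kNN
  imputation.
* **Phenotypes** — BMI = weight/height², HOMA-IR = glucose × insulin /
  22.5, the harmonized (≥ 3 of 5) metabolic-syndrome flag, and
  weight-change groups (regain/loss of ≥ 50% of LCD weight loss).
* **Differential screening** — per-gene linear mixed models
  Y = fixed effects + centre (+ subject) random intercepts + ε, Wald
  tests, Tukey-adjusted visit contrasts, Benjamini–Hochberg FDR at 5%,
  diet-regulation pattern classification, covariate-robustness and
  persistence logic, BMI-decile and weight-group marker reports.
* **Networks** — two-group sparse Gaussian graphical models with
  *intertwined* covariances αS<sub>g</sub> + (1−α)S̄, neighborhood
  selection with the AND policy, penalty calibrated to 15% edge density,
  partial-correlation edge weights
  ρ<sub>jk</sub> = −Θ<sub>jk</sub>/√(Θ<sub>jj</sub>Θ<sub>kk</sub>),
  degree/betweenness metrics, GraphML export.
* **cis-eQTL** — strand-aware cis windows (10 kb up / 15 kb downstream of
  the CDS), call-rate ≥ 95% and Hardy–Weinberg P > 0.05 filters,
  log-additive allele-dose mixed models, persistence across visits, and
  change-score associations.
* **Pipeline** — `run_pipeline()` orchestrates simulate → normalize →
  screen → network → eqtl from one seeded config into a reproducible
  artifact directory (byte-identical reruns); `validate_io()` schema-checks
  the interchange TSVs.

## Worked example

Simulate a 200-subject cohort, screen for diet-phase regulation, and
infer the sex-specific networks:

```r
library(dietexpr)

truth  <- generate_truth(sim_config(p_genes = 40), seed = 1)
cohort <- generate_cohort(truth, n_subjects = 200, seed = 1)
expr   <- generate_expression(truth, cohort, seed = 1)
pheno  <- derive_phenotypes(cohort)

fits      <- fit_gene_lmm(expr, pheno, design_spec("cid", c("centre", "subject")))
contrasts <- cid_contrasts(fits)
patterns  <- classify_diet_patterns(contrasts, alpha = 0.05)
table(patterns$label)
#>         end_down           end_up             null opposite_down_up
#>                4                3               18                9
#> opposite_up_down
#>                6
```

22 of 40 genes are called diet-regulated; against the generator's truth
this run recovers all 16 truly regulated genes (6 false calls, all weak
secondary patterns). One gene's Tukey-adjusted visit contrasts:

```r
contrasts[contrasts$gene == "G003", c("contrast", "estimate", "p", "q", "median_fc")]
#>   contrast    estimate            p            q median_fc
#> 7      2-1 -0.16134990 1.743451e-09 3.320860e-09 0.8732179
#> 8      3-1 -0.07844453 5.981503e-03 2.175092e-02 0.9331474
#> 9      3-2  0.08290536 3.337979e-03 7.027325e-03 1.0637845
```

G003 falls by 0.16 log2 units (median fold change 0.87) over the LCD and
partially rebounds during the WMD — an "opposite down–up" profile. The
network stage, on 300 draws per sex from the truth's graphical models:

```r
x    <- rbind(draw_ggm(truth, "M", 300), draw_ggm(truth, "F", 300))
nets <- infer_group_networks(x, rep(c("M", "F"), each = 300))
nets$M
#> ggm_network [M] : 40 nodes, 117 edges (density 0.150 ) at lambda 0.1034
shared_edge_fraction(nets$M, nets$F)[c("n_shared", "frac_a")]
#> $n_shared [1] 84   $frac_a [1] 71.79487
```

Both calibrated networks sit exactly at the 15% construction density
(117 of 780 node pairs), and 84 edges — 72% of each network — are shared
between the sexes, reflecting the 75% truth overlap and the intertwined
(α = 0.5) estimation. `export_network(nets$F, "women.graphml")` writes
the annotated graph for layout tools.

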