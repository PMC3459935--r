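---
title: "Models and methods behind dietexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dietexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietexpr)
```

# The setting

`dietexpr` analyses adipose-tissue gene-expression panels measured by
RT-qPCR in multi-centre dietary weight-loss trials with three clinical
investigation days: baseline (CID1), the end of an 8-week low-calorie diet
(CID2), and the end of a 26-week ad libitum weight-maintenance diet
(CID3). The package covers the full analysis path — plate quality control
and normalization, clinical phenotype derivation, gene-by-gene mixed-model
screening, two-group sparse partial-correlation networks, and cis-eQTL
association — and ships a synthetic cohort generator that reproduces the
statistical structure of such a trial together with the ground truth
needed to test every stage.

# The measurement model and normalization

A well's cycle threshold is modelled as

$$Ct_{g,w} = Ct_0 - \log_2 x_{g,s} + \pi_{p(w)} + \varepsilon_w,$$

where $x_{g,s}$ is the relative expression of gene $g$ in sample $s$,
$Ct_0$ is the cycle at relative expression 1, $\pi_p$ is an additive
per-plate offset and $\varepsilon_w$ well noise. Absent amplification is
recorded with the sentinel 999. One calibrator cDNA sample is replicated
on every plate and one water well guards against contamination.

Four normalizations are implemented:

* **delta-Ct** (`delta_ct_normalize()`): $\log_2 x = -(Ct_g - Ct_{ref})$
  within a sample. Because gene and reference share the plate, any plate
  offset cancels exactly — the method's variance floor is twice the well
  noise.
* **quantile** (`quantile_normalize()`, via `limma`): forces every
  sample column to the common distribution (row means of sorted
  columns); corrects column-wise shifts, but on biologically
  heterogeneous samples the forced common distribution redistributes
  genuine between-sample differences.
* **rank-invariant** (`rank_invariant_normalize()`): fits a monotone
  lowess mapping to the reference profile through the genes whose rank
  moves by at most 5% of the panel size. On small panels with realistic
  biological variation the invariant set can collapse; the function then
  refuses rather than extrapolating from a handful of genes.
* **geNorm reference ranking** (`genorm_rank()`): stability
  $M_j = \mathrm{mean}_k\, \mathrm{sd}_s(\log_2 x_{j,s} - \log_2 x_{k,s})$,
  iteratively discarding the least stable candidate.

`calibrator_cv()` compares methods by the coefficient of variation of the
calibrator profile across plates, on the linear expression scale, with
raw (unnormalized) data as the baseline. On the generator's default
scenario (plate offsets SD 0.3 Ct, well noise SD 0.15 Ct — chosen so that
plate effects dominate well noise, as in a well-run microfluidic system)
delta-Ct with a stable reference clearly beats both raw data and quantile
normalization, while quantile normalization does not improve on raw data;
this mirrors the empirical finding that motivated reference-gene
normalization for such panels.

Gene-level QC (`qc_filter_genes()`) drops genes whose endogenous wells
are predominantly (more than 50%) above 30 cycles or absent, and genes
whose calibrator replicates contain more than 20% outliers, an outlier
being a well beyond median ± 3 MAD across plates. The majority rule and
the MAD rule are our operationalizations of qualitative exclusion
criteria ("too low or inconsistent expression", "> 20% outliers"); both
thresholds are exposed as arguments. The MAD rule needs a spread
estimate, so it is only applied when at least 8 calibrator replicates
are available — at study scale (48 plates) this never binds. Remaining
missing values are filled by gene-space k-nearest-neighbour imputation
(`knn_impute()`, k = 10, distance-weighted mean over shared samples);
k and the metric are our choices, as the method reference names neither.

# Clinical phenotypes

`derive_phenotypes()` adds BMI ($\mathrm{kg}/\mathrm{m}^2$), HOMA-IR
(glucose [mM] × insulin [mU/l] / 22.5), the harmonized metabolic-syndrome
flag (≥ 3 of 5 criteria: waist ≥ 94/80 cm for men/women, triglycerides
≥ 1.7 mM, HDL-C < 1.03/1.29 mM, blood pressure ≥ 130/85 mmHg, fasting
glucose ≥ 5.6 mM; any missing component yields NA, never a silent
negative; medication criteria are not modelled because the simulator does
not generate them), and the weight-change group over the maintenance
phase: subjects regaining at least 50% of the weight lost during calorie
restriction are `regain`, those losing at least another 50% are `loss`,
boundaries inclusive.

# Mixed-model screening

Each gene's log2 expression is modelled with `lme4` as

$$Y_{ilk} = \beta_0 + \sum_t \beta_t X_{t,il} + C_k + (S_l) + \epsilon_{ilk},$$

with fixed terms from the design specification (visit, sex,
metabolic-syndrome status, weight, BMI, diet arm, weight-change group),
a centre random intercept $C_k$, and a subject random intercept $S_l$
whenever repeated measures enter. Skewed clinical covariates can be
logged via the specification. Inference is by Wald t tests on residual
degrees of freedom ($n - p$); the fitting engine is a standard
restricted-maximum-likelihood solver, while the package owns design
construction, contrasts and decision rules. Random-effect variances
estimated at zero are reported with a `singular` flag rather than as
failures. For speed, one model structure is fitted per design and
re-used across genes via `refit`.

Pairwise visit contrasts (`cid_contrasts()`) are adjusted family-wise
with the studentized-range (Tukey HSD) distribution on model-based
standard errors; with two levels this reduces to the ordinary two-sided
t test. Across genes, multiplicity is controlled by Benjamini–Hochberg
step-up q-values (`bh_adjust()`, FDR 5% by default). Diet-regulation
classes are assigned from the three contrasts: *opposite* regulation
requires significant baseline→LCD and LCD→WMD contrasts of opposite
sign; *end* regulation requires a significant baseline→WMD contrast; the
labels are recorded side by side, not exclusively. Median fold changes
pair visits within subject (per-subject ratios, then the median) — the
reporting convention is our interpretation, as the pairing is not
otherwise specified.

`covariate_robustness()` flags effects that stay BH-significant after a
covariate (weight, fat mass) enters the model; `persistent_signature()`
intersects significant sets across phases; `bmi_dependency_screen()`
runs the women-only per-visit BMI screen (diet arm added at CID3) and
reports top-versus-bottom BMI-decile expression ratios;
`weight_group_markers()` models the within-subject CID3−CID2 log2 change
on the weight-change group with CID2 weight and diet arm as covariates.

# Two-group sparse Gaussian graphical networks

Nodes are genes (plus any clinical variables), standardized within
group. For groups $g$ with covariances $S_g$ and pooled covariance $S$,
the *intertwined* covariance $\alpha S_g + (1-\alpha) S$ (default
$\alpha = 0.5$; the mixing weight is not pinned down by the method's
description, so it is exposed as configuration) biases both inferred
networks toward common structure, encoding the assumption of shared
functionality between the groups.

Inference is neighborhood selection: each node is lasso-regressed on all
others, solved in covariance form by coordinate descent (the solver only
needs the covariance matrix, so the same code serves raw and intertwined
inputs). An edge is kept under the **AND** policy only when both
directional regressions select it, which curbs false-positive edges. A
sparse precision estimate is rebuilt from the regressions
($\hat\Theta_{jj} = 1/\tau_j^2$,
$\hat\Theta_{jk} = -\hat\beta_{jk}/\tau_j^2$, symmetrized by averaging)
and edge weights are partial correlations
$\rho_{jk} = -\Theta_{jk}/\sqrt{\Theta_{jj}\Theta_{kk}}$. Edge
"significance" is realized by the sparsity pattern at the calibrated
penalty; no separate per-edge p-value is computed.

`calibrate_density()` bisects the penalty until the edge density (edges
divided by node pairs) is as close as attainable to the 15% construction
target used for readable networks — exact whenever the target times the
pair count is an integer on the solution path (123 edges at 41 nodes).
Ties are broken toward the smaller penalty, i.e. the denser network.
Node degree and betweenness centrality come from `igraph`; networks
export to GraphML or edge-list TSV and re-import losslessly. Because the
denominator of a "fraction of shared edges" is ambiguous,
`shared_edge_fraction()` reports the Jaccard fraction and the
intersection over each network's edge count.

# cis-eQTL association

SNPs map to genes through strand-aware closed windows: 10 kb upstream
and 15 kb downstream of the coding sequence (anchor and strand
convention are our resolution of a direction-ambiguous description, and
both extents are arguments). Genotype QC retains SNPs with call rate
≥ 95% (inclusive) and Hardy–Weinberg $P > 0.05$; the HWE test is the
1-df chi-square against allele-frequency-implied genotype frequencies,
with an exact enumeration backend available (the chi-square matches
"P > 0.05" filtering at scale; the test itself is not named by the
method description). Association uses the same mixed-model contract as
the screens: log2 expression on minor-allele dose (0/1/2,
log-additive), sex (and optionally BMI) fixed, centre random.
`eqtl_persistence()` keeps baseline-significant pairs that remain
BH-significant at both later visits; `delta_association()` tests dose
against within-subject log2 expression changes, where purely
level-acting variants are null by construction. Sex-by-genotype
independence uses the chi-square test, switching to Fisher's exact test
when any expected cell is below 5 — the standard routing, which we use
even though one description of the rule appears inverted.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults define the
study conditions every recovery and error-rate test runs under.

**Gene layer.** Two precision matrices (men, women) share a configurable
fraction (default 75%) of an Erdős–Rényi support at 15% density.
Off-diagonal magnitudes are uniform on [0.2, 0.5] with random signs —
moderate conditional dependencies typical of co-expression panels.
Positive definiteness is enforced by diagonal loading (add
$|\lambda_{\min}| + 0.1$), after which the precision is rescaled to unit
marginal variances: log2 expression SD of about 1 is what adipose qPCR
panels show, and the rescaling preserves the support and the partial
correlations exactly. Each subject draws one stable biological profile
from their sex's model; visits then add fixed effects and measurement
noise. The stable-profile design makes within-subject change scores
carry only visit effects plus noise, which is what a subject random
effect in the analysis model presupposes; redrawing profiles per visit
would make every change-score analysis structurally noisier than any
real repeated-measures design.

**Effects.** Per-gene maps: sex log2 fold change (20% of genes, 0.4–1.0),
BMI slope (20%, 0.02–0.08 per unit), metabolic-syndrome shift (15%,
0.2–0.6), diet-phase class (20% opposite down–up, 10% opposite up–down,
10% end-down, 10% end-up, magnitudes 0.3–0.7), cis-eQTL effects (25% of
genes, 0.3–0.6 per allele). Gene baseline abundances are uniform over
±4 log2 units — without abundance spread, rank- and quantile-based
normalization would be degenerate. Variance components: residual noise
SD 0.25, centre SD 0.15, subject SD 0.30.

**Cohort layer.** Eight centres, 65% women, obese baseline BMI 30–42.
Every completer loses at least the 8% LCD target (plus non-negative
noise); at CID3 a configurable fraction (default one half) regains at
least 50% of the lost weight, a quarter keeps losing, the rest stay
near their CID2 weight. Clinical variables load on a single latent
metabolic-syndrome factor per subject with fixed loadings and track
weight change across visits — enough correlation structure for the
network stage without copying any real data.

**Plates and genotypes.** Plates hold 46 sample-visits plus calibrator
and water wells; offsets and noise as above; a configurable fraction of
wells is set to the 999 sentinel and designated genes are forced above
the high-Ct threshold. Genotypes are binomial(2, MAF) per SNP;
designated violators come from an inbreeding-style heterozygote-deficit
mixture (F = 0.6), low-call SNPs get 10% missing entries; each gene
receives one SNP inside the CDS (carrying the eQTL effect if any), one
in the near flank, and one far outside any cis window.

**What is not emulated.** Amplification-efficiency differences,
standard-curve quantification, linkage disequilibrium between SNPs,
batch effects beyond additive plate offsets, attrition/dropout, and the
real study's gene-specific effect sizes. Passing tests therefore
demonstrate correctness of the statistical machinery under a faithful
but idealized data-generating process, not agreement with any real
cohort's gene lists.

# Numerical choices and problem sizes

Lasso coordinate descent converges to $10^{-10}$ coordinate change with
warm starts along the bisection path; the density bisection runs 50
iterations. Ties at the density target resolve toward the smaller
penalty. Mixed-model convergence heuristics for near-zero variance
components are silenced in the per-gene loops; degenerate fits are
caught through the singular flag and a coefficient-covariance check and
excluded with a recorded reason. The test suite exercises
false-discovery control on 200 replicate screens of 40 genes at 100
subjects (90% null), support recovery at 40 nodes with 300 samples per
group, the intertwining benefit over 20 seeds at 150 samples per group,
and parameter recovery (sex effect 1.0 at n = 500; eQTL slope 0.5 per
allele at n = 400, MAF 0.3) averaged over replicate cohorts — sizes
chosen to match the regimes the methods are meant for while keeping the
default test run fast.

# Known limitations

* The intertwined inference supports exactly two groups.
* No per-edge confidence statements; the calibrated sparsity pattern is
  the edge-selection rule.
* The qPCR model is additive on the Ct scale; multiplicative efficiency
  biases would need a standard-curve extension.
* MetS classification omits medication criteria.
* No genotype imputation, LD pruning, or trans-eQTL scan.
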