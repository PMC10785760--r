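---
title: "Methods: chemical-wide and metabolome-wide association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-wide and metabolome-wide association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dioxome` chains eight analysis stages from a targeted dioxin(-like)
congener panel and untargeted HRMS feature tables to an integrated
pathway–immune-marker network. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Study design being modeled

The intended data are from an occupational cohort of two
herbicide-producing factories: factory A (n = 76) with historically high
TCDD exposure following an industrial accident, and factory B (n = 61)
without it. Available per subject: 29 lipid-adjusted congener
concentrations (7 PCDDs, 10 dioxin-like PCDFs, 12 dioxin-like PCBs, in
ppt) with below-LOD flags; an untargeted GC-HRMS chemical feature table
(m/z 85–850); two LC-HRMS metabolome tables (C18-negative and
HILIC-positive, m/z 85–1275, triplicate injections with batch labels);
demographic covariates; and 54 immune markers in four categories (21
cytokines/growth factors, 23 hematologic parameters, 7 humoral markers, 3
lymphoma markers), measured in factory A.

## TCDD back-extrapolation

With a one-compartment first-order elimination model and half-life
$t_{1/2} = 7.1$ y, the concentration at last exposure is

$$\mathrm{TCDD}_{max} = b + \max(m - b,\, 0)\cdot 2^{\,\ell / t_{1/2}},$$

where $m$ is the measured level, $\ell$ the lag (years since last
exposure), and $b$ a steady-state background, taken as the mean measured
TCDD in factory B. Only the excess above background decays; a measurement
at or below background back-extrapolates to the background for any lag,
and factory B subjects (lag 0) keep their measured value. Whether the
original model subtracts the background before or after exponentiation is
not recoverable from the available description; we implement the
background-excess form as the default because it is the only variant under
which (i) the stated background handling is coherent and (ii)
back-extrapolation composes over consecutive lags
(`back_extrapolate_tcdd(..., subtract_background = FALSE)` gives the plain
exponential alternative). The composition (semigroup) property and
monotonicity in $m$, $\ell$ and $1/t_{1/2}$ are enforced by tests.

## Chlorine isotope screening

GC features deriving from one compound co-elute and share an abundance
profile across subjects. Pairwise similarity is

$$s_{ij} = \exp\!\left(-\frac{(1-r_{ij})^2}{2\sigma_r^2}\right)
           \exp\!\left(-\frac{(rt_i-rt_j)^2}{2\sigma_{rt}^2}\right)$$

with $r$ the Pearson correlation of log intensities, $\sigma_r = 0.5$ and
$\sigma_{rt} = 2$ s; average-linkage hierarchical clustering on $1-s$ is
cut at 0.5. These defaults keep compounds with near-perfect intensity
correlation together across a few seconds of retention jitter while
separating co-eluting but uncorrelated compounds (their similarity is at
most $e^{-2} \approx 0.14$ even at identical RT).

A cluster is screened for chlorine by locating candidate monoisotopic
peaks (no partner one $^{37}$Cl–$^{35}$Cl spacing, 1.99705 Da, below) and
collecting peaks at $M + k\cdot 1.99705$, $k \le 4$ (M+2 through M+8),
within ±5 mDa. The expected envelope is binomial,
$a_k \propto \binom{n}{k} p_{35}^{\,n-k} p_{37}^{\,k}$ with
$p_{35} = 0.7577$, normalized to the monoisotopic peak; the chlorine count
$\hat n$ minimizes the summed squared envelope error over $n = 1..10$
(ties to smaller $n$), and the fit is accepted only if every matched peak
is within 30% of its theoretical abundance. Choices worth noting:

* **±5 mDa absolute** rather than ppm: at Orbitrap-GC resolution a ppm
  window collapses at low m/z; 5 mDa also cleanly rejects the ¹³C M+1
  (and 2×M+1, spacing 2.0067) distractors, which miss by ≥ 6 mDa.
* **30% ratio tolerance** is a free parameter (upstream tooling defaults
  are not published); at the generator's 5% multiplicative intensity noise
  the envelope residuals are ≈ 7%, so the margin is wide but still rejects
  arbitrary two-peak coincidences.
* The envelope is fitted to the **cross-subject mean spectrum**;
  per-subject fitting adds noise without information when abundances are
  shared up to a scale factor.
* $n \le 10$ and $k_{\max} = 4$ bound plausible congeners in the GC scan
  range.

## Related compounds and the exposure network

A suspect is *related* to a congener when Spearman's $\rho > 0$ with
two-sided $p < 0.002$ (the screening threshold corresponding to a 20%
false-discovery level; the threshold is read as two-sided, the
conservative choice, with a one-sided flag available). The p-value uses
the t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$, adequate at cohort
n; a 10⁴-permutation oracle bounds the approximation error at small n in
the tests. Subclass sets (PCDD-, PCDF-, PCB-related) are unions over the
subclass's congeners and may overlap. The exposure network joins any
qualifying pair — targeted–targeted, targeted–related *and*
related–related (reference exposure networks mix related compounds inside
communities, so related–related edges are included) — and is partitioned
by weighted multilevel (Louvain) modularity maximization with a fixed seed
and deterministic vertex order.

## Preprocessing of feature tables

* **QC filter**: a feature is dropped when the *median across subjects* of
  its replicate CV (SD/mean on raw intensities) is ≥ 100%, or when it is
  detected (non-missing in ≥ 1 replicate — the most permissive reading) in
  < 60% of subjects. Median-over-subjects is chosen for robustness to
  single bad injections; surviving features are replicate-averaged.
* **Batch standardization**: per feature, each batch's log-intensities are
  rescaled to the pooled mean/SD. This removes additive and multiplicative
  batch effects without empirical-Bayes shrinkage; it is deliberately
  simpler than ComBat-style pooling, is the identity for a single batch,
  and passes batch-constant features through with a warning.
* **Left-censored imputation**: missing values are assumed
  below-detection-limit; per feature a normal is fitted to observed log
  intensities and missing entries are drawn from the tail truncated at the
  observed minimum (inverse-CDF, seeded). This keeps the censoring
  geometry of quantile-regression imputation approaches while staying
  transparent; observed entries are never altered.
* **Targeted panel LOD imputation**: per congener, a censored log-normal
  ML fit (`fitdistrplus::fitdistcens`) followed by the closed-form
  conditional mean $E[X \mid X < \mathrm{LOD}]$, always inside
  $(0, \mathrm{LOD})$.

All downstream analyses use natural-log intensities and ln exposures
(after imputation, so the log is defined).

## MWAS

Each ln feature is regressed on one ln exposure with ordinary least
squares; model 1 adjusts for age, factory and BMI, model 2 adds smoking
(two indicators) and alcohol. Model 1 is the default (a reference
sensitivity analysis found < 3% average coefficient deviation when adding
the extra covariates); model 2 stays behind a flag. The scan shares one QR
decomposition across all features of a mode, and equals `lm` coefficient
by coefficient to 1e-8 in tests. BH q-values are computed separately per
exposure and per mode — that is the multiplicity family — at a nominal 20%
FDR. Collinear covariates (the factory indicator in single-factory
subsets) are dropped automatically with a warning, which is what makes
per-factory subgroup runs a pure parameterization.

Aggregation reproduces the conventional congener-by-congener summary-table semantics: per
congener, features significant for the congener itself; features
significant for ≥ 1 of its related compounds (NA when it has none); their
union; and per-subclass unions that feed enrichment.

## Pathway enrichment

Features are matched to putative metabolites by adduct mass within ±5 ppm
(adduct sets: M+H, M+2H, M+ACN+2H, M+Na, M+ACN+H, M+ACN+Na, 2M+H,
M+H+H₂O for positive mode; M−H, M−H₂O−H, M+Na−2H, M+Cl, M+Hac−H, 2M−H
for negative — the occasionally seen "M + ACH + 2H" notation is read as an acetonitrile
adduct typo). The mapping is many-to-many by design. For each pathway the
overlap of significant putative metabolites against the detected
universe is scored with a one-sided hypergeometric tail, then calibrated
by drawing equally sized *feature* lists uniformly from the retained
features and recomputing:

$$p_{perm} = \frac{1 + \#\{p^*_{hyper} \le p_{hyper}\}}{n_{perm} + 1}.$$

Resampling features (not metabolites) preserves the many-to-many
annotation structure, which is the point of the mummichog strategy; the
empirical permutation p with a pseudo-count replaces the original
gamma-fit null smoothing — transparent and exact at this scale, at the
cost of a resolution floor of $1/(n_{perm}+1)$. A pathway passes at
$p_{perm} < 0.05$ with ≥ 4 significant putative metabolites ("pathway
size" counts metabolites *detected* in the data, following the detected-universe reading of such
table footnotes; a flag could redefine the universe if needed). Because
the statistic is discrete, permutation p-values are conservative
(superuniform) under the null — tests check validity, not exact
uniformity.

## Integration

Each passing pathway is summarized, over the exposed-factory subjects, by
the first principal component of the standardized ln intensities of its
significant features (single-feature pathways use the standardized
feature). PCA signs are arbitrary, so the loading of largest magnitude is
made positive — required for reproducible downstream networks. Pathway
scores X and standardized immune markers Y enter a NIPALS PLS2
(regression mode, default 3 components — the conventional default of
two-block integration tools, exposed as a parameter); the association
score is the cross-correlation reconstructed from the truncated latent
space,

$$s_{jk} = \sum_{h=1}^{H} \mathrm{cor}(x_j, t_h)\,\mathrm{cor}(y_k, t_h),$$

with $t_h$ the orthogonal X-scores. This is the natural formalization of
a score that "approximates the correlation coefficient": with
standardized variables and orthogonal scores spanning the X column space
it equals the sample correlation exactly at full rank (a tested
invariant), and truncation shrinks it toward the shared latent structure.
The p-value treats $s$ as a correlation on $n-2$ df. Edges with
$|s| > 0.3$ and $p < 0.05$ form the bipartite pathway–marker network;
isolated nodes are dropped and communities are found with the shared
Louvain routine.

## The synthetic cohort

The generator's defaults are the study conditions: 76 + 61 male workers;
ages N(69.0, 7.7²) / N(58.8, 9.0²) by factory; BMI, smoking and alcohol
matched to the reference cohort characteristics; factory-A lags uniform on 25–44 y
(blood drawn ~44 y after the accident, employment spread over decades).
Congener concentrations are log-normal — medians chosen at plausible
lipid-adjusted levels, TCDD medians 4.35 (A) vs 0.30 ppt (B) — with
dependence from a Gaussian copula (within-subclass correlations 0.5 /
0.25 / 0.95 for PCDD / PCDF / PCB, echoing the reported "moderate PCDD,
weak PCDF, r > 0.9 PCB" pattern; the true correlation matrix is not
published, so these are free parameters). Marginals are log-normal
because congener data are positive and skewed, and the copula preserves
rank correlations, which is what the selection stage consumes. LODs sit
at the 5th percentile of the factory-B marginal; censored values are
flagged, not zeroed.

Chemical features: 60 chlorinated compounds (1–8 chlorines, binomial
envelopes, ≤ 0.3 s RT jitter, 5% multiplicative intensity noise) of which
40 correlate (target r = 0.8 on the log scale) with congeners through the
copula scores, plus two-peak decoys carrying a ¹³C M+1 distractor instead
of a chlorine envelope. Chlorinated compounds are placed on a ≥ 10 s RT
grid: at the reduced feature density, random RT placement would let
mutually correlated compounds collide within the clustering kernel and
merge — a property of the synthetic density, not of the method under
test. Metabolome: 1,500 features per mode, triplicates in 2 batches
(batch shifts SD 0.5 log units), planted effects
$\ln I = \mu + \beta \ln x + 0.005\,\mathrm{age} + 0.01\,\mathrm{BMI} + \varepsilon$,
$\beta = 0.5$, $\sigma_\varepsilon = 0.5$, with affected features placed
at M−H / M+H adduct masses of metabolites from six designated pathways
(two per subclass, drivers TCDD, 23478F, PCB126); the lowest 10% of each
feature's values are left-censored; 2% of features get extreme replicate
noise to exercise the CV filter. Immune markers load (0.8) on latent
factors equal to the standardized ln driver concentrations — the same
signals that drive the pathway effects, so a complete
exposure → feature → pathway → marker chain exists by construction. The
covariate effects on the metabolome are small but nonzero so confounder
adjustment is actually exercised.

Reduced default scale (800 chemical features / 60 chlorinated, 1,500
metabolome features per mode, 25 pathways × 10 metabolites) lets the full
pipeline run in well under a minute; `sim_config(scale = "full")` restores
campaign-scale counts. All randomness flows from one seed; identical
configurations give identical outputs.

What the generator does **not** emulate — and hence what green tests do
not certify on real data: chromatographic peak shapes and profile-mode
spectra; isotopologues other than chlorine (the ¹³C M+1 is a fixed
distractor, not chemistry); RT drift; non-lognormal exposure marginals
and the true congener correlation structure; empirical-Bayes-scale batch
heterogeneity; metabolite identities (masses are synthetic); and
selection effects of a real occupational cohort.

## Numerical and degenerate-input conventions

Zero-variance features are excluded from clustering with a warning;
constant compound/congener pairs are skipped in selection; batches need
≥ 3 subjects; imputation requires ≥ 3 observed values per feature
(guaranteed post-filter); single-peak clusters can never be chlorinated;
Louvain ties are fixed by seed and sorted vertex order; envelope-fit ties
break toward fewer chlorines; PC1 signs follow the largest-loading rule;
PLS components are silently capped at the rank with a warning. Problem
sizes in the test suite (e.g. 10⁵ null pairs for selection calibration,
500 spectra for envelope sensitivity, 20 seeds for end-to-end chain
recovery) were chosen so Monte-Carlo error is small relative to the
tested margins.

## Known limitations

Batch correction is location/scale only; annotation is mass-only (no RT
library, no multistage confidence scoring, no authentic standards);
enrichment resolution is bounded by the permutation count; the PLS p-value
is approximate (a label-permutation alternative is the rigorous option at
small n); and the back-extrapolation model form is a documented
reconstruction, with the alternative exposed behind a flag.
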