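# dioxome

Integrated chemical-wide and metabolome-wide association analysis of
dioxin(-like) exposures, as an installable, fully testable R pipeline.

## The problem

Persistent chlorinated pollutants — polychlorinated dibenzo-*p*-dioxins
(PCDDs), dioxin-like dibenzofurans (PCDFs) and biphenyls (PCBs) — are
conventionally assessed one congener at a time. That misses two things:
unrecognized chlorinated *co-exposures* that travel with the measured
congeners, and the downstream metabolic footprint of the whole mixture.
`dioxome` implements the full analysis chain an exposome study of an
occupational cohort needs:

1. **Kinetics** — back-extrapolate measured plasma TCDD to its level at last
   exposure under one-compartment first-order elimination:
   `TCDD_max = bg + max(TCDD - bg, 0) · 2^(lag / t½)` with t½ = 7.1 y and the
   unexposed-factory mean as background `bg`.
2. **Chlorine screening** — group co-eluting, co-varying GC-HRMS features
   into compound spectra (correlation × retention-time kernel, average
   linkage) and flag spectra whose M, M+2, …, M+8 peaks follow the binomial
   ³⁵Cl/³⁷Cl envelope, estimating the chlorine count
   (`abundance(k) ∝ C(n,k) p₃₅ⁿ⁻ᵏ p₃₇ᵏ`).
3. **Related compounds** — suspected chlorinated compounds whose abundance
   correlates positively with any of the 29 targeted congeners (Spearman,
   two-sided p < 0.002) become "related compounds"; the combined
   exposure network is partitioned with multilevel (Louvain) community
   detection.
4. **MWAS** — each ln metabolic feature is regressed on each ln exposure
   (targeted and related) with age, factory and BMI adjustment;
   Benjamini–Hochberg FDR at 20% is applied per exposure and per LC mode,
   and hits are aggregated into PCDD(-related), PCDF(-related) and
   PCB(-related) subclasses.
5. **Pathway enrichment** — significant features are matched to putative
   metabolites by adduct mass (±5 ppm, standard positive/negative-mode
   adduct lists) and pathways are tested by a hypergeometric score
   calibrated against permuted feature lists (mummichog-style); a pathway
   passes at permutation p < 0.05 with ≥ 4 significant putative metabolites.
6. **Integration** — each enriched pathway is summarized as a PC1 score over
   its significant features; a PLS model relates pathway scores to 54 immune
   markers, and pairs with |association score| > 0.3 and p < 0.05 form a
   bipartite network with Louvain communities.

Because cohort data of this kind are not public, the package ships a seeded
**synthetic-cohort generator** (`simulate_cohort_data()`) that emulates the
study design — 137 workers in two factories with distinct TCDD
distributions, chlorinated compounds with planted isotope envelopes and
congener correlations, metabolome features with planted pathway-concentrated
exposure effects, and immune markers driven by shared latent factors — with
complete ground truth, so every stage is testable offline.

## Worked example

```r
library(dioxome)

res <- run_pipeline(pipeline_config(seed = 1))

res$suspects$table[1:3, ]
#>   cluster_id  mono_mz n_cl n_peaks      fit_rss
#> 1    CL00001 324.2634    5       5 2.716280e-04
#> 2    CL00002 476.9277    2       3 4.989430e-06
#> 3    CL00003 457.8549    4       5 4.477396e-04

head(res$related$pairs, 3)
#>   congener cluster_id       rho            p
#> 1     TCDD    CL00002 0.3878224 2.836120e-06
#> 2     TCDD    CL00004 0.4242450 2.387534e-07
#> 3     TCDD    CL00007 0.4111349 6.019030e-07

subset(res$enrichment, pass)[1:2, ]
#>   subclass   mode pathway_id overlap pathway_size     fisher_p      perm_p pass
#> 1     PCDD C18neg       PW01       8            8 1.470899e-05 0.000999001 TRUE
#> 2     PCDD C18neg       PW02       9            9 3.351414e-06 0.000999001 TRUE

res$manifest$stages$related_compounds$n_related
#> [1] 40
```

Reading the suspect table: cluster `CL00001` is a five-peak spectrum whose
envelope best fits 5 chlorines; `rho`/`p` are the Spearman statistics that
qualified a suspect as TCDD-related; `overlap`/`pathway_size` count
significant putative metabolites against metabolites detected per pathway.

With the default configuration the run takes ~15 s and reports, among other
things, 137 subjects, 60 suspected chlorinated compounds (all 60 planted
ones recovered, no decoy flagged), 40 related compounds, the six planted
pathways enriched, and an integration network with 3 communities — matching
the planted three-factor structure. `res$manifest` records seeds, parameters
and per-stage counts; setting `outdir` writes every table plus GraphML
networks.

Individual stages are plain functions on plain containers
(`feature_table`, `exposure_panel`): `back_extrapolate_tcdd()`,
`cluster_spectra()`, `detect_chlorine_envelopes()`, `spearman_select()`,
`run_mwas()`, `bh_adjust()`, `enrich_pathways()`, `pathway_pc1_scores()`,
`pls_association()`. A thin CLI lives in `inst/scripts/dioxome.R`.

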