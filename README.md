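# phenorevert

Quantifying **metabolic phenoreversion** — the return of a perturbed serum
metabotype to the healthy-population distribution — from longitudinal
quantified serum panels (NMR metabolites, lipoprotein subclass parameters,
spectral inflammation markers).

The package is written for metabolomics analysts who have cross-sectional
healthy/acute cohorts plus sparse longitudinal follow-up and want the full
chain:

1. **Screen** a discriminating variable panel: per-variable OLS on log
   values adjusted for age and sex, Benjamini–Hochberg FDR (adjusted
   p < 0.05), an effect floor of 0.5 control-SD, and greedy pruning of
   candidates correlated above Pearson r = 0.8.
2. **Discriminate** acute from healthy serum with a two-component
   **O-PLS-DA** model (one predictive component `t_pred`, one orthogonal
   `t_orth`) on the log-transformed, autoscaled panel, evaluated by
   stratified 5-fold cross-validation repeated 10 times, ROC/AUC, the
   Youden-optimal cutoff, and label-permutation tests.
3. **Project** longitudinal samples onto the model and measure the distance
   to the healthy metabotype, `D = t_pred − t̄_HC` (zero at the
   healthy-control mean; "recovered" = on the healthy side of the Youden
   cutoff).
4. **Estimate recovery times**: per subject, OLS of `t_pred` on days since
   disease onset, extrapolated to the healthy mean; the distribution of
   recovery days is fitted by maximum likelihood as a three-parameter
   **generalized extreme value** law, F(x) = exp(−(1+ξ(x−μ)/σ)^(−1/ξ)),
   with independent sub-models by clinical severity and by the 65-year age
   split.
5. **Couple inflammation**: cytokine fold changes (binary log of group mean
   ratios) with exact tie-aware Mann–Whitney tests, linear marker decay
   from day 8, and the correlation between the MCP-1 half-recovery day and
   the metabolic recovery day.

Patient-level serum data of this kind are not publicly shareable, so the
package includes a seeded **synthetic cohort generator** (log-normal
concentrations, equicorrelated lipoprotein blocks, planted acute effects in
control-SD units, GEV-distributed recovery days modulated by age and
severity, sparse bin-based sampling, a coupled 13-marker cytokine panel).
Every stage is tested end to end against it.

## Worked example

```r
library(phenorevert)

cfg    <- generator_config(seed = 1)        # 400 HC + 400 acute, 156 variables
cohort <- generate_population(cfg)

sel <- screen_panel(log(sample_matrix(cohort)),
                    as.integer(cohort$cohort == "AC"),
                    covariates = cohort[, c("age", "sex")])
head(sel[order(-abs(sel$effect_sd)),
         c("variable", "effect_sd", "p_adj", "kept_after_prune")], 5)
#>          variable effect_sd         p_adj kept_after_prune
#> 10  Phenylalanine  2.099954 4.292953e-126             TRUE
#> 5       Glutamine -2.096055 1.094005e-132             TRUE
#> 1         Glucose  1.989550 4.825207e-117             TRUE
#> 154         GlycA  1.813305 6.303014e-109             TRUE
#> 156           SPC -1.799277 1.520381e-108             TRUE
length(kept_variables(sel))
#> [1] 38
```

The screen recovers the generator's 38-variable panel: phenylalanine,
glucose and GlycA up in the acute phase, glutamine and SPC down, each
effect in control-SD units on the log scale.

The full pipeline (screen → O-PLS-DA → CV/ROC → projection → recovery →
GEV → cytokines):

```r
report <- run_pipeline(pipeline_config(seed = 1), out_dir = "out")
```

`out/report.md` then reads:

```
# Phenoreversion pipeline report

- seed: 1; config hash: bac1d7d5
- samples: 2086 (205 discarded by QC)
- selected panel: 38 variables
- out-of-fold AUC: 1.0000 (training AUC 1.0000, cutoff -1.914)
- GEV recovery-time fit: location 74.41, scale 31.35, shape 0.196 (n = 322)
- mode 68.9 d, median 86.3 d, model 95% quantile 200.8 d, empirical 95% quantile 209.8 d
```

and the returned list carries the same quantities plus the per-bin
recovered fractions and sub-models:

```r
report$recovered_fractions
#>        bin lo  hi   n   fraction
#> 1    (0,7]  0   7 250 0.00000000
#> 2   (7,14]  7  14 110 0.01818182
#> 3  (14,30] 14  30 117 0.16239316
#> 4  (30,60] 30  60 298 0.52684564
#> 5 (60,Inf] 60 Inf 111 0.88288288
report$subgroup_severity$severe$location        # 92.2
report$subgroup_severity$`mild-moderate`$location  # 69.9
```

Reading the output: the acute/healthy discrimination is essentially
perfect out of fold (AUC 1.000); 322 longitudinal subjects yield valid
linear recovery estimates; their distribution is right-skewed
(positive GEV shape) with about half of the samples collected between
day 30 and day 60 already scoring on the healthy side of the cutoff,
and recovery is slower for severe and older patients (higher sub-model
locations). The fitted location (~74 d) sits above the generating 62.44
because the default estimator, like the published one, includes
post-recovery samples that flatten the fitted slope; the
`truncate_after_recovery` option removes that bias.

## Package layout

| path | contents |
|---|---|
| `R/synthgen.R` | synthetic cohort, cytokine, spectrum and outlier generators |
| `R/preprocess.R` | day labeling, bucket integration, DBSCAN QC, log-autoscaling |
| `R/screen.R` | adjusted univariate screen, BH-FDR, correlation pruning |
| `R/oplsda.R` | O-PLS-DA fit, projection, repeated stratified CV |
| `R/evaluate.R` | ROC/AUC, Youden cutoff, permutation tests |
| `R/recovery.R` | D statistic, recovery-day estimation, recovered fractions, subgroup models |
| `R/gev.R` | GEV distribution functions and ML fitting |
| `R/inflammation.R` | Mann–Whitney (exact + approximate), fold changes, marker decay, recovery coupling |
| `R/pipeline.R` | end-to-end orchestration with file-based stages and reports |
| `vignettes/phenoreversion-methods.Rmd` | the model, assumptions, parameters and design choices |
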