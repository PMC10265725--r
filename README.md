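# pedconnectome

Longitudinal analysis of the FA-weighted structural brain connectome in
paediatric mild traumatic brain injury (mTBI) versus mild orthopaedic injury
(OI) cohorts — the comparison design used in prospective multi-site concussion
studies, where OI controls for the general effects of childhood injury and the
question is what is specific to head trauma.

The package is an end-to-end, fully seeded pipeline for researchers running
(or simulating) such studies:

1. **Network construction** — per-scan 90 x 90 adjacency matrices over the
   AAL-90 parcellation from fibre-to-region-pair assignments, edge weight =
   mean fractional anisotropy (FA); scans whose graph is not fully connected
   are excluded.
2. **Weighted graph metrics** — characteristic path length (Lp), global and
   nodal efficiency (Eg, Ne), Onnela clustering (Cp, NCp), Brandes
   betweenness (Bc), degree centrality (Dc), and small-worldness
   `sigma = gamma / lambda`, where gamma and lambda standardize Cp and Lp
   against degree-preserving, weight-multiset-preserving rewired null
   networks (default 1000 per scan). Path metrics use edge length `1/w`.
3. **Site harmonization** — covariate-preserving empirical-Bayes
   location/scale batch adjustment of the metric table (group, days
   post-injury and days², age, sex in the covariate matrix).
4. **Symptom persistence** — regression-based reliable change index:
   `z = (observed − predicted 1-month score) / SEE` from the post-on-premorbid
   regression; TBI participants with `z ≥ 1.645` are classified
   symptom-persistent, per parent and child ratings.
5. **Inference** — linear mixed-effects models
   `metric ~ Group × (Time + Time²) × (Age + Sex) [+ Hemisphere] + (1 | participant)`
   (REML, Satterthwaite df), Benjamini–Hochberg FDR over group terms
   (α = 0.05 injury; 0.025 per symptom-status rating), Cohen's d standardized
   by the total random SD with a 95%-CI robustness gate, and probing of
   significant interactions at the mean days post-injury of each assessment,
   in both sexes, and at the 10th/90th age percentiles.
6. **Synthetic cohort generator** — a first-class module producing
   participants, visits, symptom ratings and per-scan connectomes with known
   injected ground-truth effects, so every stage is testable without any data
   download.

See `vignettes/methods.Rmd` for the full model descriptions, parameter
defaults and limitations.

## Worked example

Simulate a 60-participant cohort with a known bilateral thalamic FA deficit
in the TBI group, compute metrics, harmonize, and test the thalamic nodal
clustering coefficient:

```r
library(pedconnectome)

eff <- injected_effect(c("THA.L", "THA.R"), direction = -1, magnitude = 0.08,
                       group = "TBI")
cfg <- cohort_config(n_tbi = 40, n_oi = 20, effect_spec = list(eff), seed = 7)
study <- simulate_study(cfg)          # 106 scans (25% chronic attrition)

compute_scan_metrics(study$matrices[[1]], n_null = 100, seed = 7)$global
#>         scan_id      metric  value
#> 1 P0001_chronic          Cp  0.373
#> 2 P0001_chronic          Lp  4.996
#> 3 P0001_chronic       gamma  4.625
#> 4 P0001_chronic      lambda  1.205
#> 5 P0001_chronic       sigma  3.837
#> 6 P0001_chronic          Eg  0.230
#> 7 P0001_chronic mean_degree 12.000
```

`sigma = 3.84 > 1`: the synthetic connectome is small-world (clustering far
above degree-matched random networks at comparable path length). Now the
group inference on thalamic clustering:

```r
per_scan  <- lapply(names(study$matrices), function(id)
  compute_scan_metrics(study$matrices[[id]], n_null = 0, scan_id = id))
metrics   <- metrics_long_table(per_scan)
metrics   <- metrics[!is.na(metrics$value), ]
phenotype <- merge(study$visits, study$participants, by = "participant_id")
hz        <- harmonize_metrics(metrics, phenotype)

frame <- build_design(hz$metrics, phenotype, "NCp", "nodal", region = "THA")
fit   <- fit_lmm(frame)
subset(fit$terms, term == "GroupTBI")
#>       term estimate      se  df   t        p
#> 2 GroupTBI  -0.0539 0.00384 126 -14 1.51e-27

effect_size(fit, "GroupTBI")
#>       term     d  d_lo  d_hi robust  band
#> 1 GroupTBI -5.86 -6.68 -5.04   TRUE large
```

The injected deficit is recovered: TBI thalamic clustering is lower by 0.054
(on the NCp scale) at the mean age and time, a large, robust standardized
effect (the generator's noise is small, hence the extreme d). Whole-study
runs go through one call:

```r
run_pipeline(demo_run_config("runs/demo", seed = 1))   # writes results.csv etc.
```

or from a shell via the thin CLI at `inst/scripts/pedconnectome-cli.R`
(`run-all`, `simulate`, `validate` subcommands, YAML configuration).

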