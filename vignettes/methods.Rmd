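---
title: "Methods: longitudinal weighted connectome analysis in paediatric mild TBI"
author: "pedconnectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal weighted connectome analysis in paediatric mild TBI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pedconnectome` implements a complete analysis chain for longitudinal,
multi-site studies of the structural brain connectome after paediatric mild
traumatic brain injury (mTBI), with mild orthopaedic injury (OI) as the
comparison condition. This vignette describes the statistical machinery, the
modelling assumptions behind each stage, the tunable parameters and their
defaults, and what the synthetic-cohort validation does and does not
establish.

## 1. Network construction

Each MRI scan contributes a weighted, undirected graph over the 90
supratentorial regions of the Automated Anatomical Labeling (AAL-90)
parcellation, in standard atlas order (homologous left/right pairs
alternate; odd index = left). Deterministic tractography upstream of this
package assigns each reconstructed fibre to an unordered region pair with
its mean fractional anisotropy (FA); `assemble_matrix()` sets the edge
weight of a pair to the arithmetic mean FA over its fibres, giving a
symmetric, zero-diagonal 90 x 90 matrix with weights in [0, 1].

Two deliberate conventions:

* **Edges are weights strictly greater than zero.** No minimum-fibre-count or
  weight threshold is applied, so sparsity differences between scans are
  data, not preprocessing choices.
* **Scans whose graph is not fully connected are excluded**
  (`is_fully_connected()`, `filter_scans()`), because characteristic path
  length and efficiency are undefined (infinite distances) on disconnected
  graphs. Exclusions are logged per scan.

Self-loop fibre assignments are treated as errors rather than silently
dropped: they indicate an upstream assignment bug.

## 2. Graph metrics

All metrics are weighted. Path-based metrics use edge length `1/w`, the
standard convention for FA-weighted connectomes: high-FA connections are
"short". Distances come from all-pairs shortest paths (compiled
Floyd-Warshall kernel); the test suite validates every metric against
independent brute-force oracles (exhaustive path enumeration, direct
triangle sums, literal triple-loop Floyd-Warshall).

| Metric | Level | Definition |
|---|---|---|
| Lp | global | mean shortest-path distance over unordered pairs |
| Eg | global | mean inverse distance over unordered pairs |
| Ne | nodal | mean inverse distance from a node to all others |
| Cp, NCp | global/nodal | Onnela geometric-mean triangle clustering |
| Bc | nodal | Brandes betweenness over weighted shortest paths, each unordered pair counted once, ties split by path counts |
| Dc, mean degree | nodal/global | count of strictly positive weights |
| gamma, lambda, sigma | global | Cp, Lp standardized against null networks; sigma = gamma/lambda |

**Clustering variant.** The weighted clustering coefficient is the
Onnela-type geometric-mean form with weights normalized by the network
maximum: `NCp(i) = 2/(k_i(k_i-1)) * sum_{j<h} (w'_ij w'_ih w'_jh)^(1/3)`
with `w' = w / max(w)`; nodes of degree < 2 contribute 0, and the global Cp
averages over all 90 nodes so the denominator is constant across scans.
Toolboxes differ in which weighted variant they implement; this choice is
documented here as the package's convention rather than asserted to match
any particular toolbox.

**Null networks and small-worldness.** Each scan's Cp and Lp are
standardized against a degree-preserving null ensemble: repeated
double-edge swaps (two edges (a,b), (c,d) become (a,d), (c,b)), each edge
carrying its weight, rejecting swaps that would create self-loops or
duplicate edges, with 10 accepted swaps per edge per null. This preserves
the degree sequence and edge-weight multiset exactly. Nulls that come out
disconnected are resampled so the null path length is always finite,
matching the fully-connected analysis set. The production default is 1000
nulls per scan; tests and the demo configuration use 50-100, which changes
the Monte-Carlo error of `mean(Cp_null)`, not its expectation. `sigma > 1`
indicates small-world organization.

## 3. Site (scanner) harmonization

Multi-site studies confound site with subject-level variables, so network
metrics are harmonized before inference with a covariate-preserving
empirical-Bayes location/scale batch model, fit jointly across all metric x
region features (`fit_harmonization()` / `apply_harmonization()`):

`y_gv = alpha_v + x_g' beta_v + gamma_iv + delta_iv * eps_gv`

per feature `v`, scan `g`, site `i`. The covariate matrix contains group,
days post-injury and its square, age at injury and sex — the biological
variance the adjustment must preserve. Site location and scale effects are
shrunk across features with parametric priors (normal for location,
inverse-gamma for scale) via iterative conditional updates (tolerance 1e-6,
at most 100 iterations), then removed:

`y_adj = sd_v / sqrt(delta*_iv) * (z_gv - gamma*_iv) + alpha_v + x_g' beta_v`.

Pooling all global and nodal features in one run stabilizes the EB priors
for small sites. A single-site table degenerates cleanly to the identity
(with a warning). Repeated scans of one participant are treated as
independent observations at this stage; the longitudinal structure is
modelled downstream. The test suite cross-checks the adjusted values
against the reference `sva::ComBat` implementation.

## 4. Symptom persistence: regression-based reliable change

Post-concussive symptom totals (e.g. Health and Behaviour Inventory) are
rated by parents retrospectively for the premorbid period and by parents
and children at 1 month post-injury. For each rater, 1-month totals are
regressed on parent premorbid totals in a reference sample; a participant's
reliable change score is

`z = (observed - predicted) / SEE`, `SEE = sqrt(sum(resid^2)/(n-2))`,

and TBI participants with `z >= 1.645` (one-tailed 5%; a *significant
increase* is directional) are classified as having persistent symptoms. The
cutoff and the reference-sample composition are parameters
(`threshold_z`, `reference = "all"` or `"oi"`): the default reference is
all participants with complete pairs, but an OI-only reference is the
cleaner choice when the TBI distribution is expected to be contaminated by
true symptom increases, and it is what the calibration tests use. OI
participants are never reclassified; TBI participants without a 1-month
rating are excluded from symptom-group analyses and logged. Child ratings
are regressed on *parent* premorbid ratings; no child premorbid rating
exists.

## 5. Mixed-effects inference

For each metric (global) or metric x homologous-region pair (nodal, left
and right entering as rows with a hemisphere covariate), the model is

```
value ~ Group * (Time + Time2) * (Age + Sex) [+ Hemisphere] + (1 | participant)
```

fit by REML with `lmerTest`, Satterthwaite degrees of freedom for the
fixed-effect t-tests. `Group` is either the 2-level injury factor
(reference OI) or the 3-level symptom-status factor (OI,
TBI-non-persistent, TBI-persistent; per rater). Numerical and
interpretability choices:

* **Time** is days post-injury centred at the sample mean and scaled by its
  SD *before* squaring: raw days² over a 2-200 day range is badly
  conditioned and highly collinear with days.
* **Age** is centred at the sample mean. With three-way interactions in the
  model, an uncentred age would make the Group main effect the group
  difference extrapolated to age 0 — meaningless for a cohort aged 8-17.
  After centring it is the group difference at the average age, which is
  also what the follow-up probes report.
* Sex reference is male; hemisphere reference is left. Hemisphere enters as
  a main effect only (a hemisphere-moderation check is available as a
  diagnostic, not a gate).
* If fewer than two participants have repeated rows the participant
  variance is unidentifiable and the fit degenerates, with a warning, to
  ordinary least squares with zero participant variance.

**Multiplicity.** Benjamini-Hochberg FDR is applied within the declared
family: all group-involving terms across the 45 region pairs for a given
metric and grouping (or the single model's group terms, for global
metrics), at corrected alpha 0.05 for the injury comparison and 0.025 for
each symptom-status comparison (two raters). Non-converged models are
excluded from the family with a warning.

**Effect sizes.** Cohen's d for a term or probed contrast is the estimate
divided by the total random SD, `sqrt(var_participant + var_residual)` —
the model's subject-level SD; bands follow the conventional |0.20|, |0.50|,
|0.80| boundaries and an effect is *robust* only when the 95% CI of d
(`(estimate +/- 1.96 SE)/SD`) excludes zero.

**Interaction probing.** Where group interactions survive FDR, the group
contrast is evaluated as a linear combination of fixed effects at: the mean
observed days post-injury of each assessment (post-acute, ~3-month and
~6-month chronic assignments, computed from the analyzed sample), both
sexes, and the 10th/90th percentile of age at injury, each with d, CI and
the robustness gate. Grid points outside the observed covariate range are
computed with a warning.

## 6. The synthetic cohort generator

`cohort_config()` / `simulate_study()` generate a complete study with known
ground truth. Defaults encode the target design: 360 TBI / 196 OI
participants, five sites, 59% male, ages 8-16.99, a post-acute scan at 2-33
days (mode near 10 days, via a clipped gamma), a chronic scan randomly
assigned to ~90 or ~180 days (jitter SD 7 days) with 25% attrition, and
parent premorbid plus parent/child 1-month symptom ratings.

Connectomes start from one cohort-shared template: a Watts-Strogatz ring
lattice over 90 nodes (mean degree 12, rewiring probability 0.1) with edge
weights drawn once from Beta(8,8) scaled to [0.2, 0.8] — connected,
small-world, FA-plausible. Per scan, edges receive (in order): a linear age
effect (0.002 FA/yr by default, giving harmonization covariate signal to
preserve), any matching injected ground-truth effects (edge deltas on all
edges incident to target regions, conditioned on group, latent symptom
status, sex, age band and days post-injury), the site's additive and
multiplicative effects, and independent Gaussian edge noise (SD 0.02);
weights are clipped to (0.01, 1] so FA stays bounded and no edge is
deleted. Site effects act on edge weights *before* metric computation, so
harmonization is tested against realistic (nonlinear) propagation into the
metrics rather than against additive noise on the metrics themselves.

Symptom scores follow the regression structure the RCI assumes: premorbid
totals are rounded Gamma(2, rate 0.4) draws; 1-month totals are
`1 + 0.8 * premorbid + shift + N(0, 3)`, rounded and floored at zero, with
shift 0 for OI, +1 for non-persistent TBI and +6 (two residual SDs — a
reliable increase) for latent-persistent TBI (22% of TBI participants).

The template topology, weight law, site effects and symptom model are
stand-ins — the underlying study reports none of these distributions — and
all are configuration-exposed. Consequently, passing recovery tests shows
that the *pipeline* is correct and calibrated under a realistic data
structure; it does not validate distributional claims about real FA
networks, real scanner effects (which can be spatially structured and
non-multiplicative), real symptom dynamics, or real missingness (attrition
here is random, not informative). One consequence worth noting: apart from
the age trend, the generator has no between-participant edge variability,
so subject-level variance in the metrics is far smaller than in real
cohorts and standardized effect sizes (Cohen's d) on synthetic runs can be
much larger than field-realistic values even for modest raw differences.

## 7. Reproducibility and problem sizes

A single global seed deterministically derives per-stage and per-scan
streams, so `run_pipeline()` with a fixed configuration reproduces every
output byte-identically. All artifacts are plain text (CSV, JSON,
whitespace-delimited matrices). The demo configuration
(`demo_run_config()`: 60 TBI / 30 OI, 50 nulls per scan, a reduced metric
set) exercises every stage in about a minute; validation simulations in the
test suite use 100-600 scans, 200 replicates for type-I calibration, 25
replicates for coefficient recovery, and 10,000 draws for RCI calibration —
sizes chosen so each check's Monte-Carlo error is comfortably inside the
tolerance it asserts.

## 8. Known limitations

* Deterministic tractography, parcellation registration and image-level QC
  are upstream and out of scope; the pipeline starts at fibre-to-region-pair
  assignments.
* Only the parametric (normal / inverse-gamma) harmonization priors are
  implemented; non-parametric and longitudinal batch variants are not.
* The FDR family definition, the Cohen's d standardizer and the df method
  are fields where published studies are often silent; the package pins
  documented defaults (family = group terms per metric x grouping across
  regions; d standardized by total random SD; Satterthwaite df) rather than
  claiming a unique convention.
* Binary-matrix variants, streamline-count weighting, thresholded networks,
  rich-club and modularity analyses are intentionally not provided.
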