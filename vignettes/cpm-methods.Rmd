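---
title: "Connectome-based predictive modelling with cpmconn: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modelling with cpmconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Connectome-based predictive modelling (CPM) asks whether a behavioural
score — here, symptom severity on an ADOS-like scale in an autism cohort —
can be predicted from a subject's whole-brain resting-state functional
connectivity.  Each subject contributes a symmetric $N \times N$ matrix of
Fisher-z transformed Pearson correlations between region-of-interest (ROI)
time courses ($N = 160$ nodes in six canonical networks by default, giving
$E = N(N-1)/2 = 12720$ edges).  The protocol is deliberately simple and
fully data driven:

1. **Edge selection.** For each edge, compute the partial correlation
   between edge weight and behaviour across training subjects, controlling
   for nuisance covariates (age, sex, mean framewise displacement).  Edges
   with two-sided $p < 0.01$ enter the *positive* network if the partial
   $r$ is positive, the *negative* network if negative.
2. **Network strength.** Sum each subject's selected edge weights per
   tail, each undirected edge once.
3. **Tail model.** Ordinary least squares of behaviour on strength (one
   predictor plus intercept), separately per tail.
4. **Leave-one-out cross-validation (LOOCV).** Steps 1–3 are repeated $n$
   times with one subject held out; the held-out subject's score is
   predicted from the fold's own mask and model.  Model performance is the
   partial correlation (same covariates) between the $n$ pooled LOOCV
   predictions and the observed scores, with $df = n - 2 - k$.
5. **Consensus network.** Edges selected in *every* fold; encoded as an
   $N \times N$ matrix over $\{-1, 0, +1\}$.
6. **Permutation inference.** The behaviour vector is shuffled against
   the connectomes (covariates stay with the connectomes) and the whole
   LOOCV repeated; $p_{\mathrm{perm}} = (1 + \#\{r_{\mathrm{null}} \ge
   r_{\mathrm{obs}}\}) / (1 + n_{\mathrm{perm}})$, one-sided, because
   predictive validity is directional.
7. **Transfer.** The consensus mask plus a slope/intercept refit on the
   full model sample are applied unchanged to an independent patient
   sample (replication) and to healthy controls (specificity, an
   expected-null test).
8. **Anatomy.** Node degree and the $K \times K$ within/between-network
   edge counts summarize the consensus network for circle/glass-brain
   plotting.

Because multi-site consortium data carry scanner and acquisition effects,
edge features are first harmonized with an empirical-Bayes location/scale
(ComBat) model that removes per-site additive offsets and scale factors
while explicitly preserving variance explained by biological covariates.

# Statistical details and conventions

**Edge order.** All flat edge representations use one canonical order: the
row-major upper triangle $(1,2), (1,3), \dots, (1,N), (2,3), \dots$.
`vectorize()`/`devectorize()` are exact inverses and every mask, feature
table and export uses this order.

**Fisher z.** $z = \operatorname{atanh}(r)$ after clipping $r$ to
$\pm(1 - 10^{-7})$; clip counts are reported.  Diagonals are stored as 0
and never enter any edge statistic.

**Partial correlation.** Pearson correlation of OLS residuals of $x$ and
$y$ on $[1, X]$; $p$ from the $t$ distribution with $df = n - 2 - k$.
Covariates are z-scored within each fold's training subjects before
residualization (numerically inert, but keeps designs well conditioned).
A covariate that is *constant* within a training fold — a real occurrence
with a 94 % male cohort and LOOCV — is dropped from the projection for
that fold, exactly as `lm()` would pivot it out; the selection threshold
keeps the nominal $k$.

**Selection threshold.** Thresholding two-sided $p <$ `p_threshold` is
implemented as $|r| > r_c$ with $r_c = \sqrt{t_c^2 / (t_c^2 + df)}$, which
avoids $E$ p-value evaluations per fold and is exact.

**Degenerate folds.** A fold with no surviving edges predicts its
training mean and is flagged; a model whose folds are all empty is marked
invalid.  Note that training-mean predictions are perfectly
*anticorrelated* with the left-out observation (the leave-one-out mean
artifact), so null-permutation evaluation correlations skew negative
rather than centring exactly at zero; the one-sided permutation p value
is calibrated regardless (verified by simulation in the test suite).

**Permutation engine.** The fold sweep processes the observed behaviour
and all permuted copies in one pass: per fold, edges are residualized
once, and edge–behaviour correlations, selections, training strengths and
the held-out prediction for all $P$ behaviour columns reduce to three
BLAS-level matrix products.  A 200-permutation LOOCV at $n = 150$,
$E = 12720$ runs in well under a minute on one core.  The same sweep's
first column yields the observed `cpm_result`
(`permutation_test(detail = TRUE)`).

**FDR.** Benjamini–Hochberg step-up, applied within each pre-registered
family (one family per validation sample batch).

# Harmonization model

For subject $s$ at site $i$ and edge $e$:
$y_{se} = \alpha_e + X_s \beta_e + \gamma_{ie} + \delta_{ie}
\varepsilon_{se}$.  After a standardization step that fits $\alpha_e$,
$\beta_e$ and a pooled variance, per-site location and scale estimates are
shrunk toward priors pooled across edges — Gaussian for $\gamma$,
inverse-gamma for $\delta$ — and removed; the covariate contribution
$X_s \beta_e$ is restored.  Both the parametric iterative solution
(default: fast, deterministic) and the nonparametric weighted-likelihood
solution are implemented; both reproduce the reference empirical-Bayes
implementation to numerical precision in the test suite, and both must
pass the same simulation contracts.  The nonparametric integral is
$O(E^2)$ per site and is intended for moderate feature counts.

Two properties of the estimator worth knowing:

* With realistic residual noise the removed offset leaves a residual
  between-site mean difference of order the EB-shrunk sampling noise
  (about half the standard error of a site-mean difference), *not* zero;
  complete per-feature removal is only observed when the offset dominates
  the noise.
* With a single site there is no between-site variability to remove, and
  the input is returned unchanged.

Harmonization is applied once per sample (model, validation and control
samples separately) *before* CPM, replicating the common order of
operations in multi-site studies.  This leaks a small amount of pooled
site-effect information across CV folds (never behaviour).  For
methodological comparison, `loocv_cpm_strict()` offers the leakage-free
alternative: each fold fits the site model on its training subjects only
and transforms the held-out subject with `combat_apply()`; it refits the
EB model n times and is accordingly slower, so the pipeline default
remains the pooled convention.  One further sampling-frame choice: the
minimum-site-size exclusion is a modelling-cohort criterion and is not
applied to the small specificity (control) sample.

# The synthetic cohort generator

`generator_spec()`/`generate()` produce a replica of the emulated study's
structure, with defaults frozen to its printed design:

| parameter | default | meaning |
|---|---|---|
| `n_model`, `n_validation`, `n_control` | 151 / 172 / 36 | sample sizes |
| `n_nodes` | 160 | six-network connectome |
| `n_true_neg` | 40 | planted negative edges |
| `beta` | 1.5 | z-units of edge weight per SD of behaviour |
| `noise_sd` | 1 | per-edge noise SD (abstract z units) |
| score means/SDs | ADOS-like | total 11.89 ± 4.00 (model), 10.38 ± 3.91 (validation), 1.33 ± 1.66 (controls) |
| covariate effects | age 0.2, sex 0.1, mfd 0.3 | slopes on latent behaviour, SD units |
| sites | 5 / 5 / 2 | per-site additive offsets (SD 0.15) and scale factors (log-SD 0.15), per-edge effects drawn Gaussian / inverse-gamma |

Behaviour is generated *first* (baseline + covariate effects + noise);
planted edges then add $\mathrm{sign} \cdot \beta \cdot
\operatorname{std}(b_s)$ to their baseline weight, so negative-network
edges are literally anticorrelated with severity, matching the dominant
negative-network phenomenology the design emulates.  Control subjects
draw scores from the healthy-range distribution and receive *no* edge
coupling, making specificity tests null by construction.  Age is
Uniform(7, 40), sex Bernoulli(0.92 male), mean FD lognormal with mean
≈ 0.09 mm — conventions chosen once to match the emulated cohort table,
overridable in the spec.  One global seed drives fixed substreams
(truth, site effects, phenotype, edge noise, time series), so identical
`(spec, seed)` give bit-identical datasets.

At the default `beta = 1.5` against unit noise the planted edge–behaviour
correlation is $\approx 0.83$, far stronger than real rsFC–behaviour
effects; this is the calibration at which edge selection at $p < 0.01$
and $n = 150$ recovers ≥ 90 % of planted edges, which is what makes
ground-truth recovery a usable acceptance surface.  Consequently the
generator validates the *machinery* (selection, cross-validation,
inference, transfer), not effect sizes: passing tests say nothing about
attainable prediction accuracy on real consortium data, where $r$ around
0.2 is typical.  The generator also omits autocorrelated BOLD noise,
motion artifacts and realistic haemodynamics by design.

`timeseries_from_connectome()` inverts the pipeline front end for
testing: Gaussian series whose population correlation is
$\tanh(z_{\mathrm{target}})$ (nearest-positive-definite repair via
`Matrix::nearPD` when needed, reported), so `compute_connectome()`
recovers the target within $\sim 1/\sqrt{T-3}$ per edge.

# Numerical and design choices

* **Separate tails.** Positive and negative networks are modelled and
  evaluated as separate single-predictor models, since study reports list
  per-tail r values; a combined two-predictor model is deliberately out
  of scope.
* **Two-sided selection p, sign decides the tail** — standard CPM
  practice when a report states only a threshold.
* **Transfer coefficients** are refit on the full model sample over the
  consensus-mask strengths, not averaged across fold models:
  deterministic and uses all training data.
* **Missing subscores** drop subjects per-analysis, not globally, so
  different scores legitimately have different $n$ (and $df$).
* **Subtype analyses** reuse the same code path on filtered subject
  subsets with a minimum-n gate (default 30; undersized subsets are
  skipped with a logged reason).
* **Site-size filtering** runs after all row-level exclusions and is
  re-evaluated on whatever table it receives, which makes filtering
  idempotent.
* **Scan truncation** to a common length is available as an optional
  generator/filter-level choice but off by default; the emulated cohort
  truncated only one site's scans.
* **Permutation p** uses the add-one estimator, so the smallest
  attainable value is $1/(n_{\mathrm{perm}}+1)$.

# Problem sizes used by the shipped checks

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make each property measurable while keeping a full run on one
core comfortable: oracle checks at $N \le 20$; the leakage audit at
$N = 20$, $n = 40$; permutation calibration over 200 replicate null
datasets at $n = 60$, $N = 30$, 200 permutations; ground-truth recovery
and transfer over 20 seeds at the full $N = 160$, $n = 150/170/36$ design
with 200 permutations; harmonization contracts at $n = 120$ with 500
features.  The analysis scripts under `analysis/` run the full-size
replica once (200 permutations) and write their tables under `results/`.

# Known limitations

* Image-derived exclusion criteria (signal loss, bad normalization,
  coverage) cannot be computed from a phenotype table; they are accepted
  as pre-computed boolean QC columns.
* The LOOCV evaluation correlates predictions pooled across folds;
  fold-wise averaging variants are not implemented.
* ComBat variants with nonlinear age terms (ComBat-GAM) or covariance
  harmonization (CovBat) are out of scope.
* k-fold/split-half CV and sparse/ridge CPM variants are out of scope.
* The bundled 160-node atlas is synthetic: network sizes follow the
  canonical six-network split, but labels and MNI coordinates are
  placeholders, so anatomical claims should use a user-supplied atlas.
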