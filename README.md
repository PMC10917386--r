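# cpmconn

Connectome-based predictive modelling (CPM) of behaviour from whole-brain
resting-state functional connectivity, in R.

## What this package is for

CPM is the standard data-driven protocol for asking whether a behavioural
or clinical score can be predicted from a subject's functional connectome
— here modelled on predicting autism symptom severity (ADOS-like scores)
in a multi-site resting-state cohort.  Each subject contributes a
symmetric `N x N` matrix of Fisher-z transformed Pearson correlations
between ROI time courses (160 nodes in six canonical networks by
default).  The protocol:

1. select edges whose partial correlation with the score (controlling
   age, sex, head motion) passes `p < 0.01`, split by sign into a
   *positive* and a *negative* network;
2. sum each subject's selected edge weights into per-tail **network
   strengths**;
3. fit a one-predictor linear model of score on strength;
4. embed 1–3 in **leave-one-out cross-validation**; performance is the
   partial correlation `r` between pooled LOOCV predictions and observed
   scores, tested against a permutation null built by reshuffling the
   score–connectome correspondence and rerunning the whole LOOCV;
5. keep the **consensus network** (edges selected in every fold), and
   transfer it, with coefficients refit on the full model sample, to an
   independent patient sample (replication) and to healthy controls
   (specificity — an expected-null test);
6. summarize network anatomy as node degrees and `6 x 6`
   within/between-network edge counts.

Because multi-site data carry scanner effects, edge features are first
harmonized with an empirical-Bayes location/scale (ComBat) model —
implemented in the package, parametric and nonparametric — that removes
per-site additive offsets and scale factors while preserving covariates
of interest.

A synthetic cohort generator plants a known negative edge set coupled to
the behaviour (plus confounded covariates and per-site effects), so the
entire pipeline is testable by recovery of ground truth.  See
`vignettes/cpm-methods.Rmd` for the model, assumptions and design
choices.

## Worked example

A reduced planted dataset: 60 model-sample patients, 30-node connectome,
10 planted negative edges.

```r
library(cpmconn)

spec <- generator_spec(n_model = 60, n_validation = 40, n_control = 20,
                       n_nodes = 30, n_true_neg = 10)
ds  <- generate(spec, seed = 42)
mod <- ds$pheno$sample == "model"
cov <- cbind(age = ds$pheno$age[mod],
             sexM = as.numeric(ds$pheno$sex[mod] == "M"),
             mfd = ds$pheno$mfd[mod])

perm <- permutation_test(ds$edges[mod, ], ds$pheno$score_total[mod], cov,
                         p_threshold = 0.01, n_perm = 200, seed = 7,
                         detail = TRUE)
perm$observed
#> Leave-one-out CPM (n = 60, p < 0.01, k = 3 covariates)
#>   pos tail: r = 0.090 (df = 55, parametric p = 0.504), 1 consensus edges, 0/60 empty folds
#>   neg tail: r = 0.955 (df = 55, parametric p = 1.18e-30), 10 consensus edges, 0/60 empty folds
perm
#> CPM permutation test (200 shuffles, seed 7)
#>   pos tail: r = 0.090, p_perm = 0.2687, mean null r = -0.0957
#>   neg tail: r = 0.955, p_perm = 0.004975, mean null r = -0.0741
```

The negative network predicts the planted severity score almost
perfectly (`r = 0.955` across held-out subjects; permutation `p` at the
add-one minimum `1/201`), while the positive tail — which has no planted
edges — stays at chance.  All 10 consensus edges are the planted ones:

```r
all(ds$truth$true_positions %in% perm$observed$consensus$neg)
#> [1] TRUE
```

Transfer to the independent validation sample replicates the model:

```r
tm  <- transfer_model(ds$edges[mod, ], ds$pheno$score_total[mod],
                      perm$observed$consensus$neg)
val <- ds$pheno$sample == "validation"
external_validate(tm, ds$edges[val, ], ds$pheno$score_total[val],
                  cbind(age = ds$pheno$age[val],
                        sexM = as.numeric(ds$pheno$sex[val] == "M"),
                        mfd = ds$pheno$mfd[val]))
#> External validation on 'validation' (n = 40, 10 consensus edges): r(df=35) = 0.969, p = 8.049e-23
```

and the consensus network's anatomy is summarized per atlas network:

```r
summarize_network(consensus_mask(perm$observed, 30), ds$atlas)
```

## The full study replica

`run_pipeline(run_config(seed = ...))` chains every stage — simulate (or
load your own edge/phenotype tables), filter subjects on exclusion
criteria, harmonize each sample across sites, fit CPM per score and
subtype subset with permutation inference, validate on the independent
samples with BH-FDR per family, and export anatomy tables — writing
summaries, masks, predictions, a log and a manifest to an output
directory.  The numbered scripts under `analysis/` run the same workflow
as a narrative, full-size analysis (151/172/36 subjects, 160 nodes),
writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # cohort description
Rscript analysis/02_filter.R     # exclusions by criterion
Rscript analysis/03_harmonize.R  # site-effect attenuation
Rscript analysis/04_cpm.R        # LOOCV + permutation per score
Rscript analysis/05_validate.R   # replication & specificity
Rscript analysis/06_anatomy.R    # degrees & network-pair counts
```

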