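# daesurv

Unsupervised feature extraction from paired tumor omics with tied-weight
denoising autoencoders, and a survival-association pipeline on top of the
extracted features.

## The problem

Bulk tumor cohorts are routinely profiled on several omics layers at once —
here gene-expression read counts and gene-level log2 copy-number values
over the same patients. Each layer is high-dimensional and noisy, and
neither alone tells you whether the cohort splits into clinically distinct
subgroups. `daesurv` compresses each layer, and both jointly, into 100
"deep feature" activities per patient using denoising autoencoders, then
runs the downstream clinical analysis: patient clustering, association
tests against clinical characteristics (receptor status, stage, pathology),
per-feature Cox survival fits, a coefficient-weighted risk score with
high/low-risk stratification, and trace-back of the learned weights to
ranked gene lists for enrichment tools.

## The model

One-input architecture (per omics source), tied weights:

```
encode = sigmoid(W' x + b)         W : genes x 100
decode = sigmoid(W encode + b')
```

Two-input architecture: each source is encoded to 1000 units, the encodes
are concatenated (2000) and mapped to 100 feature units; the decode path
reuses the transposes of the same matrices in reverse order. Training
corrupts a fraction (default 0.25) of each patient's gene values to zero,
and minimizes the mean binary cross-entropy between the reconstruction and
the clean input by plain SGD (learning rate 0.1, batch size 64, 100
epochs), with 50% inverted dropout after the feature layer. The feature
activities are the sigmoid encode outputs on the clean input.

Downstream, each feature's activity is scored against overall survival with
a univariate Cox proportional-hazards fit, h(t) = h0(t) exp(b x)
(Newton–Raphson on the Breslow partial likelihood), and patients receive
the risk score r = Σ b_i a_i, binarized at the 55% quantile into high- and
low-risk groups. Gene-level weights are W_g = W B (B the vector of Cox
coefficients), filtered at |W_g| ≥ 0.01.

A synthetic paired-omics generator (`simulate_bundle()`) plants latent
factors shared by both layers, a two-group patient structure, an ER-like
label, and a factor-linked exponential hazard, so every stage of the
pipeline can be validated against known ground truth.

## Worked example

```r
library(daesurv)

b  <- simulate_bundle(sim_config(n_patients = 150, n_genes = 500,
                                 group_effect = 8, hazard_coef = 0.8,
                                 seed = 7))
pp <- preprocess_bundle(b)
#> preprocess: expression 475 -> 467 genes (filter), matched 442 genes x 150 patients

fit <- dae(pp$cna, hidden = 100, epochs = 100, seed = 7)
fit
#> Denoising autoencoder (one-input, tied weights)
#>   442 genes -> 100 features
#>   150 patients, 100 epochs trained, final mean BCE 0.7031

cl <- hier_cluster(fitted(fit), k = 2)
cl
#> Hierarchical clustering (complete linkage, euclidean distance), k = 2
#> cluster
#>  1  2
#> 78 72

association_table(cl, pp$clinical, fields = c("er_status", "stage"))
#>   characteristic     fisher_p      chisq_p odds_ratio
#> 1      er_status 4.722918e-19 4.884877e-18       34.1
#> 2          stage 2.928064e-01 2.850780e-01         NA

ct      <- cox_feature_table(fitted(fit), pp$clinical$os_time,
                             pp$clinical$os_event)
profile <- binarize_risk(risk_score(fitted(fit), ct))
profile
#> Risk profile: cutoff 54.5072 (quantile 0.55)
#>  low high
#>   82   68

evaluate_risk_groups(profile, pp$clinical$os_time,
                     pp$clinical$os_event)$report
#>         hr   ci_low  ci_high        cox_p    logrank_p
#> 1 1.065314 1.051006 1.079817 4.680934e-20 6.861644e-36
```

Reading the output: the clusters split 78/72 and align almost perfectly
with the planted ER-like label (Fisher p ≈ 5e-19) but not with the
unplanted stage variable (p ≈ 0.29); the continuous risk score carries a
hazard ratio of 1.065 per unit with a log-rank split of the high/low
groups at p ≈ 7e-36 — the planted survival signal, recovered end to end.

`run_pipeline(pipeline_config(...), outdir)` executes the whole flow
(simulate/load → preprocess → three model fits → cluster → associate →
risk → trace-back) and writes every artifact as tab-separated text plus a
`summary.json`. A thin command-line wrapper with per-stage subcommands
lives at `inst/scripts/dae_pipeline.R`.

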