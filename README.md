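# arqsar

QSAR modelling and virtual screening for steroidal androgen-receptor (AR)
antagonists, built around the 7α-substituted dihydrotestosterone (DHT)
antagonist series.

AR antagonists such as bicalutamide are first-line endocrine therapy for
prostate cancer, and resistance in advanced disease drives the search for new
chemotypes. `arqsar` implements the complete in-silico workflow used to
prioritise candidate steroidal antagonists for that search:

1. **Descriptor curation** — removal of constant/near-constant molecular
   descriptors and iterative pruning of descriptor pairs with |Pearson r| >
   0.98 (`remove_constant()`, `prune_correlated()`).
2. **GA-MLR model selection** — a genetic algorithm searches fixed-size
   descriptor subsets; each chromosome is scored by the Friedman lack-of-fit
   of its ordinary-least-squares fit,

   LOF = SSE / (1 − (c + d·p)/n)²,

   with p descriptors, c = p + 1 basis functions, smoothness d = 0.5 and n
   training compounds (`qsar_gamlr()`, `run_ga()`, `friedman_lof()`).
3. **Validation** — R², RMSE, leave-one-out and leave-many-out Q², the
   external predictivity family Q²F1/F2/F3, Lin's concordance correlation
   coefficient, and Y-scrambling against chance correlation
   (`validation_metrics()` and friends).
4. **Applicability domain** — leverage h = x(XᵀX)⁻¹xᵀ with cutoff
   h\* = 3(p + 1)/n, Williams-plot data for labelled compounds and
   Insubria-graph data for unlabelled screening compounds
   (`leverages()`, `williams_points()`, `insubria_points()`).
5. **Virtual screening** — apply a frozen model to a compound library,
   attach inside/outside-domain flags, rank by predicted pIC50
   (`screen_compounds()`, `top_hits()`).
6. **MM/GBSA bookkeeping** — compose binding free energies
   ΔG_bind = ΔE_MM + ΔG_sol − TΔS from precomputed per-complex term tables
   and filter per-residue decompositions (`binding_free_energy()`,
   `rank_complexes()`, `key_residues()`).

Because the commercial descriptor software behind the original data is
proprietary, the package ships a synthetic-data generator
(`generate_synthetic()`) that reproduces the *statistical* shape of the study
— 29 training / 7 external / 110 screening compounds, ~358 curated
descriptors, a planted four-descriptor linear signal, near-duplicate decoy
pairs and constructed leverage outliers — so every stage is exercised by
tests without any external input. The reference study tables (activity data,
the frozen four-descriptor model, 110 screening predictions, MM/GBSA energy
terms) are packaged as plain-text fixtures, available via
`dht_antagonists()`.

## Worked example

Reference data and the frozen published model:

```r
library(arqsar)

fx  <- dht_antagonists()
tr  <- fx$activity[fx$activity$split == "train", ]
ext <- fx$activity[fx$activity$split == "pred_a", ]

fx$model
#> MLR model: pIC50 = 27.13 - 2.89*IC5 + 1.01*GATS5e - 3.17*DISPp - 12.99*HATS3u
#>   fitted on n = 29 compounds

q2_f1(ext$experimental_pIC50, ext$predicted_pIC50, mean(tr$experimental_pIC50))
#> [1] 0.7356685
leverage_cutoff(4, 29)
#> [1] 0.5172414

top_hits(as_screen_result(fx$screen), k = 3)
#> Top screening hits
#>   best overall:   CID_70126881 (predicted pIC50 7.90, AD N)
#>   best inside AD: CID_70128824 (predicted pIC50 7.37)
#>    compound_id predicted_pIC50  h ad_flag rank
#> 1 CID_70126881            7.90 NA       N    1
#> 2 CID_70127147            7.76 NA       N    2
#> 3 CID_70127446            7.54 NA       N    3
```

The Q²F1 value (0.736) is the external predictivity of the frozen model on
the seven prediction-set-a compounds: 1 minus the ratio of the external
squared prediction error to the external deviation from the training mean.
The leverage cutoff 0.517 bounds the structural applicability domain of the
four-descriptor model; the top screening hit inside that domain is
CID_70128824, while the two higher-ranked compounds are extrapolations
(flag `N`).

Fitting a model on synthetic data with planted ground truth:

```r
d   <- generate_synthetic(synthetic_spec(seed = 42))
tr  <- d$activity$split == "train"
cur <- prune_correlated(remove_constant(d$descriptors)$table)$table
fit <- qsar_gamlr(unclass(cur)[tr, ], d$activity$pIC50[tr], model_size = 4,
                  config = ga_config(seed = 42, stagnation_patience = 100))
fit
#> GA-MLR QSAR model
#>
#> MLR model: pIC50 = 6.484 + 0.5695*D049 - 0.5072*D074 + 0.8006*D153 - 0.7256*D321
#>   fitted on n = 29 compounds
#>   R2 = 0.982   RMSE = 0.189   Q2(LOO) = 0.975   LOF = 1.8015
d$ground_truth$names
#> [1] "D049" "D074" "D153" "D321"
```

The GA recovered exactly the four planted descriptors out of 358 columns.
`summary(fit, ...)` adds leave-many-out Q², external statistics and
Y-scrambling; `plot(fit)` draws the Williams plot; `run_pipeline()` chains
every stage and writes all artefacts plus a manifest.

## Notes on the packaged data

The packaged activity table keeps every value exactly as published. The
predicted value of training compound 7 (6.76) is inconsistent with the
published training statistics (R² = 0.760, RMSE = 0.226), which are only
reproduced with 5.76; `dht_antagonists(correct_compound7 = TRUE)` applies
that correction explicitly, and the `anomaly` element documents it. The
descriptor values of the 110 screening compounds were never published, so
their predictions and domain flags are consumed as given; the screening
*logic* is exercised on synthetic data instead.
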