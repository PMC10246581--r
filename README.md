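# yieldmil

Attention-based multiple instance learning for multi-modal grain yield
prediction in plant breeding trials.

## The problem

Breeding programs decide which wheat lines to advance from per-plot grain
yield (t/ha). Genomic prediction ranks lines from SNP dosages before any
field data exist but ignores the environment; phenomic prediction from UAV
imagery tracks the growing crop but cannot rank unsown lines. `yieldmil`
implements a single model that fuses both: each plot is a *bag* of
instances — multispectral, thermal and elevation (DEM) images across
irregular flight dates, plus the line's genotype — and yield is predicted
from the whole bag. Trained multi-modally, the model can still predict from
genotypes alone, which is the scenario of genomic selection in a new
environment.

## The model

Any permutation-invariant set function decomposes as
*S(X) = g(Σ<sub>x∈X</sub> f(x))*. Accordingly: per-source encoders *f*
map every instance to a 256-dim embedding (residual CNN or pooled-statistic
MLP for images, a 1024/512 fully connected stack for genotypes), a learned
attention pooling combines them,

&nbsp;&nbsp;&nbsp;&nbsp;*z = Σᵢ aᵢ hᵢ*, &nbsp;
*aᵢ = softmax(wᵀ tanh(V hᵢᵀ))ᵢ*,

and a final fully connected regressor *g* emits yield, trained end-to-end
under MSE. Multiple attention heads are concatenated; optional one-hot date
and channel encodings are appended to embeddings. The weights *aᵢ* sum to
one and are the interpretability surface: mass per channel and per flight
date shows what the model used. The package also ships the classical
baseline pipeline (NDVI/NDRE/GNDVI + band moments aggregated into four
date groups; lasso and random-forest regressors), grouped/trial-stratified
evaluation protocols, marker harmonization and genotype-only fine-tuning
for cross-environment prediction, selection-gain curves, genotype QC
filters, and a seeded synthetic breeding-trial generator that makes every
stage testable without external data.

## Worked example

A 240-plot synthetic season (120 lines × 2 replicates, heritability 0.5,
eight flights, only multispectral images carry yield signal), trained on
one 80/10/10 entry-grouped split:

```r
library(yieldmil)

cfg <- sim_config(n_lines = 120, n_reps = 2, seed = 1,
                  image_size = c(16, 16), thermal_signal = 0, dem_signal = 0)
ds <- simulate_dataset(cfg)

plan <- make_splits(ds$samples, repeats = 5, seed = 1)
tr <- split_samples(ds$samples, plan, 1, "train")
va <- split_samples(ds$samples, plan, 1, "val")
te <- split_samples(ds$samples, plan, 1, "test")

model <- mil_model(model_config(encoder_scale = "tiny",
                                genotype_hidden = c(256, 128), n_heads = 4,
                                bag_size = 8),
                   marker_ids = ds$genotypes$marker_ids,
                   date_vocab = as.character(cfg$flight_dates), seed = 1)
fit <- train_model(model, tr, va,
                   train_config(lr = 1e-3, epochs = 20, patience = 8), seed = 1)

pred <- predict_samples(fit, te)
obs <- vapply(te, `[[`, 0, "yield")
evaluate(pred, obs)
#> metrics (plot level, n=24): MAE 0.744 t/ha | MSE 0.963 | Pearson 0.944 | R2 0.455

cor(predict_samples(fit, te, genotype_only = TRUE), obs)
#> [1] 0.374

round(attention_by_channel(fit, te)$head_mean, 3)
#> multispectral       thermal           dem      genotype
#>         0.880         0.010         0.066         0.044

selection_gain_curve(pred, obs, fractions = c(0.1, 0.2, 0.4))
#>   fraction n_selected mean_yield
#> 1      0.1          3   6.982656
#> 2      0.2          5   7.035629
#> 3      0.4         10   6.802981
```

Reading the numbers: the multi-modal model reaches Pearson 0.94 on held-out
entries; the same trained model restricted to the genotype instance still
ranks lines usefully (r = 0.37, near the h² = 0.5 ceiling given 96 training
entries); the attention mass concentrates on the multispectral channel —
the only one carrying signal in this simulation; and selecting the top 10%
of plots by prediction realizes a mean yield of 6.98 t/ha against a
population mean of 5.77 t/ha.

## Documentation

The methods vignette (`vignettes/multimodal-yield-mil.Rmd`) documents the
model and its assumptions, all tunable parameters with defaults and units,
what the synthetic generator does and does not emulate, numerical choices,
and known limitations.
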