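---
title: "Multi-modal attention MIL for grain yield prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal attention MIL for grain yield prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

Breeding programs measure grain yield per *plot* — a sown rectangle of one
genetically unique *entry* (line), replicated across *trials*. Two families
of predictors exist: genomic prediction from SNP dosages, which works before
any field data exist but ignores the environment, and phenomic prediction
from UAV imagery, which tracks the growing crop but requires flying the
field. `yieldmil` implements a model that fuses both: each plot is a *bag*
of instances — its multispectral images, thermal images, digital elevation
models (DEMs) across flight dates, plus its genotype — and yield is a
function of the whole bag.

Any permutation-invariant set function can be written as
$S(X) = g\left(\sum_{x \in X} f(x)\right)$ for suitable transformations
$f$ and $g$, which motivates the three-step architecture: encode every
instance to a fixed-size embedding, pool the embeddings with a
permutation-invariant operator, and regress yield from the pooled vector.
The pooling here is learned, gated attention: for embeddings
$H = \{h_1,\dots,h_k\}$,

$$z = \sum_{i=1}^k a_i h_i, \qquad
a_i = \frac{\exp(w^\top \tanh(V h_i^\top))}
           {\sum_j \exp(w^\top \tanh(V h_j^\top))},$$

with $V \in \mathbb{R}^{l \times m}$, $w \in \mathbb{R}^l$. The weights
$a_i$ are a softmax over gated scores, so they are nonnegative, sum to one,
and double as an interpretability surface: the mass on an instance measures
its contribution to the prediction. Several heads pool the bag
independently and their outputs are concatenated before the final
fully connected regressor. Training minimizes the mean squared error
$\mathcal{L} = \sum_i (\hat{y}_i - y_i)^2 / N$.

Because image counts vary per plot and per date — and whole data sources
may be missing — the bag formulation is essential: absent channels simply
contribute no instances, and a model trained multi-modally can still
predict from the genotype instance alone.

## Architecture choices

* **Per-source encoders, 256-dim embeddings.** Images pass through one
  encoder per channel; genotypes through a fully connected network with
  hidden widths 1024 and 512. All encoders emit 256-dimensional vectors.
* **Image encoder scales.** `encoder_scale = "resnet"` is a residual CNN
  on raw pixels (im2col convolutions with hand-derived gradients; the
  classic 18-layer layout is `conv_blocks = c(2, 2, 2, 2)`,
  `conv_base_width = 64`, the package default is a compact
  `c(2, 2)`/width-16 variant). Batch normalization is omitted: it adds
  train/eval mode divergence and contributes little at these widths.
  Single-band channels (thermal, DEM) enter through a learned 1x1 channel
  adapter. `encoder_scale = "tiny"` replaces pixels with pooled band
  statistics (mean, sd, quadrant means per band) through a small MLP; it
  is the default because channel-level statistics carry essentially all
  of the simulated signal and train in seconds on a single CPU.
* **Attention gate width** $l$ defaults to 128 — a mid-sized gating layer
  between the embedding (256) and the scalar logit.
* **Temporal and channel encodings.** Optional one-hot blocks appended to
  each embedding: one slot per training flight date plus a reserved
  *other* slot (cross-environment prediction guarantees unseen dates, so
  they map there rather than erroring), and one slot per data source.
  Genotype instances receive an all-zero date block.
* **Bag subsampling.** During training at most `bag_size` images per
  channel are drawn uniformly without replacement, fresh at every
  iteration; inference always uses all instances, which removes evaluation
  stochasticity and makes predictions exactly permutation invariant.
* **Numerics.** Softmax with max-subtraction; tanh in the attention gate,
  rectifiers in the encoders; He/Xavier initialization matched to each
  layer's nonlinearity; Adam with decoupled weight decay; yields are
  standardized internally during training (predictions are mapped back to
  t/ha), which makes convergence insensitive to the large yield
  intercept; a non-finite loss aborts with the epoch, batch and learning
  rate in the message.

One genuinely open layout question is whether each channel should be
pooled separately and the pooled vectors fused afterwards, or all
instances pooled jointly in one bag. `yieldmil` pools jointly — a single
attention (per head) over the union of image and genotype embeddings —
which keeps the channel-mass interpretation straightforward and lets the
gate trade sources off against each other directly.

## Training protocol

Splits are grouped by entry (replicate plots of a line never straddle
partitions, which would leak genetic identity into the test set) and
stratified by trial, at 80/10/10 train/validation/test fractions with 5
repeated random splits by default. A note on conventions: repeated
grouped-stratified splitting at 80/10/10 is used rather than classic
5-fold partitioning (which would imply 20% test folds); the printed
fractions and the repeat count are both honored, the fold interpretation
is not. Entries replicated across trials are stratified by their majority
trial with a warning. Partition sizes are allocated by largest remainder
over per-trial entry quotas, so realized fractions are exact to one
entry's granularity.

Training tracks validation Pearson per epoch, returns the best-epoch
weights, and stops early after a configurable patience (the stopping rule
is this package's choice; it bounds desk-scale runs). Learning-rate
schedules: none, plateau (halving after a stall), and cyclic cosine
annealing. Hyperparameters are tuned by random search (default 20 draws)
over the grid {learning rate 1e-5/1e-4/1e-3, schedule, batch 8/16, bag
8/16/32, heads 1/4/8, temporal on/off, channel on/off}, selecting on
validation Pearson.

For cross-environment genomic selection the model is trained
multi-modally in environment A, markers of environment B are harmonized
to the trained panel (absent markers filled with the stored training mean
dosage; a hard error below 50% overlap), and the model is fine-tuned for
a few epochs on genotype-only bags of environment A's own training split
— image encoders frozen, learning rate scaled by 0.1. Environment B's
yields are never touched during adaptation.

## Baseline featurization

The classical comparison pipeline reduces each multispectral image to 16
features: mean and mode of the five bands (blue, green, red, rededge,
nir) and of three vegetation-index maps,

$$\mathrm{NDVI} = \frac{NIR - Red}{NIR + Red},\quad
\mathrm{NDRE} = \frac{NIR - RedEdge}{NIR + RedEdge},\quad
\mathrm{GNDVI} = \frac{NIR - Green}{NIR + Green},$$

computed per pixel with zero-denominator pixels masked. The *mode* of a
continuous pixel distribution is implemented as the center of the most
populated of 256 equal-width bins over the band's observed range, ties
to the lowest bin — deterministic and resolution-controlled. Indices are
computed per pixel and then summarized (rather than from band means);
the switch is a one-liner in `channel_moments()` if the alternative is
wanted. Features are averaged over a plot's images within each of four
date groups (a named 2018-season preset ships in
`season2018_grouping()`; arbitrary datasets default to four
quantile-balanced groups), giving 16 features per group or 64
concatenated. Groups without images are masked and imputed with
training-set feature means at fit time. Baselines are an L1-penalized
linear model (glmnet, penalty by internal cross-validation) and a random
forest (ranger, `mtry`/node size by internal cross-validation).

## The synthetic trial generator

No public dataset accompanies the package; the generator produces
datasets with the statistical structure the model assumes, so every
stage is testable end to end. Its components, with defaults:

* **Genotypes.** Per-marker allele frequency uniform on `maf_range`
  (default 0.1–0.5); inbred-line sampling with exact allele frequency and
  expected heterozygosity `het_rate` (default 3%, typical residual
  heterozygosity of inbred wheat); i.i.d. missingness (default 5%).
* **Genetic architecture.** `n_causal` markers (default 20 of 200) with
  Gaussian effects; breeding values standardized to unit variance.
* **Field design.** Lines assigned to `n_trials` trials, `n_reps`
  replicates; yield = 6 t/ha + g + trial effect (sd 0.3 t/ha) + residual,
  with the residual sd derived so that narrow-sense heritability equals
  `h2_target` (default 0.5) — mid-range for wheat yield trials.
* **Canopy dynamics.** A logistic mean growth curve over eight flights
  spanning late January to mid-March, shifted per plot by its
  standardized yield deviation through a Gaussian separation window
  peaking at mid-season. Consequently the correlation between image
  signal and yield peaks at mid-growth *by construction*, making the
  known biology (flowering and grain fill determine yield) a testable
  recovery target for the attention mechanism.
* **Images.** Multispectral band means are parameterized so that
  image-level NDVI equals the latent health exactly at zero noise; the
  NDVI perturbation sd is 0.03 at the mid-season peak and 4x larger at
  the season edges. Thermal is inversely related to health with the
  largest noise (sd 0.15); DEM tracks cumulative growth with a
  line-stature factor, hence informative late. The `thermal_signal` and
  `dem_signal` amplitudes can be set to zero to render those channels
  pure noise. Image counts are Poisson (mean 3 per plot, date and
  channel), emulating irregular acquisition including zero-image dates.
  Pixel-level texture noise (sd 0.02) is added everywhere.

What the generator does *not* emulate: real optics and radiometry,
spatial texture within a plot, spatially correlated field trends,
genotype-by-environment interaction, linkage disequilibrium between
markers. Passing recovery tests therefore demonstrates that the
machinery extracts the signals it was built for — not that it matches
any particular field campaign's accuracy.

## Scales used by the test suite

The recovery experiments in the test suite run on a 240-plot fixture
(120 entries x 2 replicates, 6 trials, h² = 0.5, 16x16-pixel images,
200 markers with 20 causal, thermal and DEM signal amplitudes set to
zero so only multispectral images carry yield information), with tiny
encoders throughout — pooled-statistic image encoders and a 256/128
genotype stack — and three seeds. These sizes are the package's choice
of a desk-scale experiment: large enough for the qualitative findings
(multimodal beats genotype-only; attention concentrates on the
informative channel and the mid-season window) to be stable across
seeds, small enough to run routinely. The full-size architecture
(residual CNN encoders, 1024/512 genotype stack) is exercised for
correctness (gradient checks against finite differences, batching and
determinism contracts) rather than trained to convergence.

## Known limitations

* Pure-R tensor operations: throughput is adequate for hundreds of
  plots with compact encoders, not for hundred-thousand-image campaigns.
* Mean-dosage imputation of missing genotype calls is the standard
  genomic-prediction default, but no LD-aware imputation is provided.
* Multi-allelic VCF records are rejected rather than split; the intended
  input is biallelic SNP calls from genotyping-by-sequencing pipelines.
* The attention summaries report per-head masses and a head mean; no
  cross-head aggregate beyond the mean is defined. Date masses are
  renormalized within dated instances so the genotype instance does not
  dilute the temporal picture; both choices are documented here because
  reasonable alternatives exist.

## A minimal session

```{r example}
library(yieldmil)

cfg <- sim_config(n_lines = 120, n_reps = 2, seed = 1)
ds <- simulate_dataset(cfg)

plan <- make_splits(ds$samples, repeats = 5, seed = 1)
tr <- split_samples(ds$samples, plan, 1, "train")
va <- split_samples(ds$samples, plan, 1, "val")
te <- split_samples(ds$samples, plan, 1, "test")

model <- mil_model(model_config(encoder_scale = "tiny",
                                genotype_hidden = c(256, 128)),
                   marker_ids = ds$genotypes$marker_ids,
                   date_vocab = as.character(cfg$flight_dates), seed = 1)
fit <- train_model(model, tr, va,
                   train_config(lr = 1e-3, epochs = 20), seed = 1)

pred <- predict_samples(fit, te)
obs <- vapply(te, `[[`, 0, "yield")
evaluate(pred, obs)

attention_by_channel(fit, te)$head_mean
```
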