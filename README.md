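# libramix

Denoising for single-cell antigen-barcode (LIBRA-seq style) UMI counts.

In barcoded-antigen B cell screens, the UMI count linking a droplet to an
antigen mixes true binding signal with technical noise: ambient barcodes
captured without their antigen, and antigens stuck to cells
non-specifically. The conventional LIBRA-seq score (LSS; centered
log-ratio then per-antigen Z-score, binding called at LSS ≥ 1) does not
model that noise and admits false positives. libramix fits, per sample and
antigen, a two-component negative binomial mixture

P(k) = ω·NB(k | n₁, p₁) + (1−ω)·NB(k | n₂, p₂),   NB(k | n, p) = C(k+n−1, n−1) pⁿ(1−p)ᵏ,

by direct maximum likelihood (log-sum-exp NLL, optimization on
log/logit-transformed coordinates), labels the higher-median component as
signal, and converts each count into a Bayes posterior signal probability
P_S(k). When a sample contains engineered negative-control cells
(identified by heavy-chain CDR3 within 5% edit distance of the control
antibody's CDR3), a single NB fitted to their counts seeds the noise
component; otherwise a percentile split of the donor counts initializes
both components. High-confidence binding calls combine both scores:
LSS ≥ 1 AND P_S ≥ 0.9.

The package is aimed at analysts of antigen-barcode B cell screens who
want probabilistic noise assignment instead of a single count or score
threshold, plus the supporting machinery: model-family comparison
(Poisson/Gaussian mixtures, AIC/BIC), bootstrap stability analyses, and a
ground-truth synthetic data generator.

## Worked example

```r
library(libramix)

ds <- generate_dataset(preset_scenarios()$well_separated)
ctrl  <- names(ds$truth$is_control)[ds$truth$is_control]
donor <- names(ds$truth$is_control)[!ds$truth$is_control]

init <- init_from_control(ds$counts[ctrl, 1], ds$counts[donor, 1])
fit  <- fit_mixture(ds$counts[donor, 1], init)
fit$params <- assign_labels(fit$params)
fit$params
#> <nb_mixture> omega = 0.7262
#>   noise : n = 2.1774, p = 0.70622 (median 1)
#>   signal: n = 24.677, p = 0.2382 (median 78)

res <- classify(ds$counts[donor, 1], fit$params, threshold = 0.5)
mean(res$call == ds$truth$labels[donor, 1])
#> [1] 1
```

The generating truth for this scenario is a 70/30 noise/signal mix of
NB(2, 0.7) (mean ≈ 0.86) and NB(20, 0.2) (mean 80): the fitted weight
(0.726 on the noise-labeled component) and component parameters recover
it, and thresholding the posterior at 0.5 reproduces every generating
label. End to end from files:

```r
run_simulate(preset_scenarios()$well_separated, "demo")
cfg <- run_config(counts_path = "demo/counts.csv", bcr_path = "demo/bcr.tsv",
                  output_dir = "demo/out", seed = 1)
run_denoise(cfg)   # writes params.json, calls.tsv, report.json, config.json
```

## Vignette

`vignettes/denoising-methods.Rmd` documents the model and its
assumptions, the two initialization strategies, preprocessing rules,
numerical choices, and what the synthetic generator does and does not
emulate.
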