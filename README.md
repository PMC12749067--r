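# mwdensity

Frequency-based breast-density classification from multistatic microwave
S21 scans.

## The problem

Breast density (the proportion of fibroglandular versus fatty tissue)
raises cancer risk and masks tumours in mammography. Microwave imaging
senses dielectric contrast instead of radiographic opacity: a transmitter
and a receiver rotate around the breast (10 Tx stops, 80 Rx stops every
4.5°) while a vector network analyser sweeps 1–9 GHz in 5 MHz steps,
yielding one complex `800 × 1601` S21 matrix per scan. High-density (HD)
breasts scatter more and show richer angular oscillation and
frequency-dependent structure than low-density (LD) breasts — structure a
classifier can pick up directly from the calibrated S-parameters, with no
image reconstruction.

`mwdensity` is for signal-processing and ML researchers working with such
scans: it provides the scan containers, the feature extraction, the
evaluation harness, and — because the clinical scans are not publicly
deposited — a moment-calibrated synthetic scan generator to exercise the
whole pipeline.

## The method

Each scan is split into ten `80 × 1601` per-transmitter blocks `M^(t)`.
After per-receiver DC removal (subtracting each row's complex mean over
frequency), two unnormalized DFTs are taken per block,

    spectral:  X[i, k] = Σ_n S21[i, n] e^(−j2πkn/F)   (along frequency)
    spatial:   X[k, j] = Σ_n S21[n, j] e^(−j2πkn/R)   (along receivers, R = 80)

The first K = 40 components of each are split into magnitude |X| and
principal-value phase ∠X, and each is pooled into a mean μ and population
standard deviation σ, giving 8 statistics per block and an 80-dimensional
feature vector per scan (`8 × 10` Tx); in sub-band mode each selected
1 GHz band SB1–SB8 contributes its own 8 × 10 statistics. Features are
z-scored with training-set parameters and fed to standard classifiers
(k-NN, naive Bayes, SVM-RBF/linear, trees, forests, boosting) under a
Monte-Carlo (5 × stratified 80/20) plus inner 4-fold protocol. Performance
is scored by the balance rate

    BR = (2 − (sensitivity + specificity)) + |sensitivity − specificity|

(0 = perfect and balanced, 2 = one class ignored), and a sub-band search
ranks band combinations by BR on identical splits. A density-stratified
detection harness compares cancer detection with and without routing test
samples through per-density models.

## Worked example

```r
library(mwdensity)

# one synthetic high-density scan and its spatial statistics at 4 GHz
scan <- generate_scan("HD", seed = 1)
scan
#> <s21_scan> HD_healthy_1: 800x1601 complex, density=HD, health=healthy
estimate_spatial_moments(scan, 4e9)
#> # A tibble: 1 × 4
#>         f_hz     mean       std    cv
#>        <dbl>    <dbl>     <dbl> <dbl>
#> 1 4000000000 0.000122 0.0000516 0.422
```

One scan's spatial std (5.16e-5) and CV (0.42) scatter around the HD
calibration anchors (5.73e-5, 0.46); the generator contract is that
200-scan ensemble averages recover them to within 5%.

```r
# a small labelled dataset, extracted straight to features, then evaluated
feats <- generate_feature_table(n_per_cell = 5, seed = 42)
dim(feats)
#> [1] 20 83       # sample_id, density, health + 80 features

rep <- evaluate_classifier(feats, "density", classifier_spec("svm_rbf"),
                           split_plan(seed = 1))
glance(rep)
#> # A tibble: 1 × 14
#>   classifier phase total_accuracy_mean total_accuracy_sd sensitivity_mean ...
#> 1 svm_rbf    test                    1                 0                1 ...
```

Even 10 scans per class separate perfectly — the synthetic class contrast
(23% more spatial variability and 3× more angular harmonics in HD) is an
easy target at these sizes. The balance rate reproduces published worked
values from class-accuracy pairs:

```r
balance_rate(0.6738, 0.7552)
#> [1] 0.6524     # prints as 0.65 at two decimals
```

Sub-band search and density-stratified detection follow the same pattern:

```r
ds <- generate_dataset(n_per_cell = 10, seed = 7)
subband_search(ds$scans, c("1000 0000", "0010 0000", "1011 1100"))
autoplot(rep)
```

A command-line driver wraps the same functions
(`Rscript inst/cli/mwdensity.R simulate --out scans --n-per-cell 5 --seed 1`,
then `extract`, `evaluate`, `subband-search`, `detect`; every run writes a
`manifest.json` it can be reproduced from).

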