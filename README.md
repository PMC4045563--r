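# mfractal

Multiscale fractal analysis and classification of grayscale images.

## The problem

Texture changes in medical images — for example the diffuse structural
changes that Alzheimer's disease produces in T2-weighted brain MRI — alter
how image intensity fluctuates across scales. `mfractal` quantifies that
structure with a small, fast, whole-image feature set: the image is
flattened into a 1D signal by row concatenation, the signal's multiscale
scaling is summarized by six generalized Hurst exponents, and the resulting
feature vectors are classified with a polynomial-kernel support vector
machine under leave-one-out cross-validation (LOOCV). No segmentation,
region-of-interest definition or image reduction is required.

The package is aimed at researchers in quantitative image analysis who
want a compact fractal characterization of images (or of any 1D signal)
and a reproducible classification harness around it.

## The method

For a signal *S*(*t*), *t* = 1..*T*, moment order *q* and lag *d*, the
structure function is

    K_q(d) = < |S(t+d) - S(t)|^q >_t  /  < |S(t)|^q >_t

(numerator averaged over the T − d valid start points, denominator over all
T samples). Self-affine signals obey K_q(d) ∝ d^(q·H(q)), so an OLS fit of
log K_q(d) against log d over d = 1..19 gives the generalized Hurst
exponent H(q) = slope / q for each q = 1..6. H(2) is the classic Hurst
exponent: 0.5 for a random walk, above 0.5 for persistent signals, below
for antipersistent ones. The six-component vector (H(1), …, H(6)) is the
image feature.

Classification uses a soft-margin SVM with the inhomogeneous polynomial
kernel K(x, y) = (x·y + 1)^degree (default degree 4, penalty C = 1,
features z-scored from the training fold), with LOOCV reporting the
correct classification rate (CCR), sensitivity and specificity.

Because real MRI cannot ship with the package, it includes exact synthetic
ground truth: ±1 random walks, fractional Brownian motion via Davies–Harte
circulant embedding, and two-class fractal textures by 2D spectral
synthesis.

## Worked example

```r
library(mfractal)

# a fractional Brownian motion path with known Hurst exponent 0.7
x <- generate_fbm(65536, hurst = 0.7, seed = 1)
hurst_spectrum(x, q_values = 1:6, d_max = 19)
#> Generalized Hurst spectrum H(q):
#>  q      H  slope r_squared
#>  1 0.7057 0.7057         1
#>  2 0.7047 1.4095         1
#>  3 0.7050 2.1151         1
#>  4 0.7060 2.8241         1
#>  5 0.7074 3.5370         1
#>  6 0.7090 4.2540         1
```

The spectrum is flat across q (monofractal, as fBm should be) and H(2)
recovers the generating Hurst parameter to within 0.005. On images:

```r
ds <- generate_dataset(n_per_class = 10, class_roughness = c(0.3, 0.7),
                       seed = 1, height = 128, width = 128)
evaluate_loocv(ds[, paste0("H", 1:6)], ds$label,
               svm_config(degree = 4), ids = ds$image_id)
#> Leave-one-out cross-validation (20 samples)
#>   CCR:         100.00% +/- 0.0000
#>   Sensitivity: 100.00% +/- 0.0000
#>   Specificity: 100.00% +/- 0.0000
#>   Kernel degree 4, C = 1, standardize = TRUE
```

The two texture classes differ only in their spectral roughness (0.3 vs
0.7); their Hurst feature vectors separate them perfectly in this run.

## Command line

A thin wrapper is installed at `inst/cli/mfractal`:

```sh
Rscript inst/cli/mfractal simulate fbm --out fbm.csv --seed 1 --hurst 0.7
Rscript inst/cli/mfractal analyze-signal --signal fbm.csv --out spectrum.csv
Rscript inst/cli/mfractal extract --images images/ --out features.csv
Rscript inst/cli/mfractal evaluate --features features.csv --out report.json
```

Every command writes a `*_manifest.json` recording the full configuration
and seed, so any output is regenerable. Exit codes: 0 ok, 1 usage error,
2 data error.

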