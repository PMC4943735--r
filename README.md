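# pattsig

Are two classes of animal color patterns actually *visually
distinguishable*, or only distinguishable to the human who sorted them?
pattsig implements a receiver-independent pipeline for answering that
question from calibrated photographs, aimed at behavioral ecologists and
students of animal coloration — the kind of study where a color-changing
lizard's seasonal and courtship patterns are classified by eye and the
classification needs an objective check.

The pipeline has three parts:

1. **Visual signatures.** Each photograph is calibrated against an
   in-frame white standard (per-channel gain to a reference region),
   cropped to the body, and encoded as a fixed-length signature of
   C2-type features: Gabor-filter responses at 16 scales × 4
   orientations are max-pooled into a shift-tolerant C1 representation
   over the luminance channel (grayscale pathway) or over luminance plus
   eight rectified single-opponent color channels (red–green,
   yellow–blue, red–cyan, white–black; color pathway); the signature's
   *i*-th coordinate is the maximal Gaussian similarity
   exp(−‖patch − t_i‖² / 2σ²) between template *t_i* — one of a
   dictionary sampled at random image locations in four size classes —
   and the best-matching location across all positions and scale bands.
   Because the grayscale pathway is blind to constant-luminance color
   changes, the paired color/grayscale analysis tells pattern apart
   from mere color.

2. **Distinguishability.** Two labeled classes are compared by the
   leave-one-out success rate of a linear SVM (libsvm, C = 1), with
   significance from a label-permutation test that recomputes the full
   LOO loop per shuffle: p = (1 + #{null ≥ observed}) / (m + 1). A
   pairwise driver produces the full class-pair table with optional
   Holm correction, and an unknown-assignment mode trains on two
   classes and assigns a third group (reporting per-class fractions
   and whether the group is separable from each class at all).

3. **Field statistics and synthetic data.** Uncorrected 2×2 chi-square,
   exact binomial tests, ML logistic regression with likelihood-ratio
   tests (e.g. P(brown) ~ month + SVL seasonal color-change models),
   and one-way ANOVA with Tukey HSD; plus a generator of synthetic
   pattern-class images (base color / stripes / blotches, with a
   white strip so calibration is exercised end-to-end, and a
   *separation* dial that interpolates class specs toward their mean)
   and of capture-metadata tables with a known logistic structure, so
   every stage is testable without field photographs.

See `vignettes/visual-signatures.Rmd` for the models, parameter
defaults, and design decisions.

## Worked example

```r
library(pattsig)

# Two synthetic pattern classes (plain brown "A" vs bright striped green
# "F"), 6 images each, full pipeline in the color pathway:
ds <- synthetic_signature_run(default_pattern_specs()[c("A", "F")],
                              n_per_class = 6, size = c(96, 96),
                              separation = 1.5, mode = "color", seed = 42,
                              n_templates = 100)
permutation_p_value(ds, n_permutations = 199, seed = 7)
#> LOO success rate 1 on n = 12 ; permutation P = 0.005 ( 199 permutations, seed 7 )
```

Every one of the 12 held-out images was assigned to its own class, and
no permuted labeling matched that rate, so P takes its smallest
attainable value, 1/200: the two classes are distinguishable.

```r
# A 2x2 contingency test: 11 of 36 males of one color morph showed a
# behavior that 0 of 47 of the other morph did
r <- chi2_2x2(11, 25, 0, 47)
sprintf("chi-square(1) = %.1f, P = %.3g", r$statistic, r$p_value)
#> "chi-square(1) = 16.6, P = 4.73e-05"

# Seasonal color change: simulate capture records where the log-odds of
# brown rise by 0.416 per month and fall by 0.289 per cm of body length,
# then recover the model by maximum likelihood with LR tests
md <- generate_metadata(n = 148, seed = 1)
md$brown <- as.integer(md$color == "brown")
fit <- logistic_fit_lr(md, "brown", c("month", "svl"))
fit$coefficients
#>      month        svl
#>  0.3697921 -0.2508315
fit$lr_tests
#>    term  lr_chisq df      p_value
#> 1 month 13.562585  1 0.0002307392
#> 2   svl  7.600396  1 0.0058355493
```

A single n = 148 sample estimates both slopes with the right signs and
magnitudes (sampling error of roughly ±0.1 at this n); both terms are
significant by likelihood ratio.

A thin command-line front end over the same functions is in
`inst/scripts/pattsig-cli.R` (synthetic data, signatures,
distinguishability tables, field statistics); users with their own
photograph corpus can run `analyze_image_corpus()` on a directory of
images plus a labels CSV.

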