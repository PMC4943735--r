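---
title: "Visual signatures and pattern distinguishability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual signatures and pattern distinguishability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pattsig answers a question that recurs in studies of animal coloration:
given photographs of animal bodies sorted into candidate pattern classes
(say, the seasonal and courtship color patterns of a color-changing
lizard), are those classes *visually distinguishable*, or are they an
artifact of the human observer's sorting? The package answers it with a
receiver-independent image representation, a classifier, and a
permutation test, plus the supporting field statistics such a study
needs and a synthetic-data generator that makes the whole pipeline
testable without photographs.

## The image representation

Photographs taken in the field are not comparable pixel-for-pixel:
illumination varies between shots. The first stage therefore rescales
each image against an in-frame *white standard* (e.g. a white ruler
photographed beside the animal): each channel is multiplied by the gain
`g_c = target_c / mean_c(reference region)` and clipped to [0, 1]
(`calibrate_white()`). This is the single-patch "white patch" model —
a per-channel linear gain with no offset — applied to gamma-encoded
sRGB values in [0, 1]. The image is then cropped to the body extent
(`crop_body()`; all rectangles in the package are 0-based and
half-open) and, for feature extraction, downscaled by exact area
averaging so its longer side is at most 256 px by default
(`resize_max_side()`). Working on encoded values with a linear gain is
the simplest model consistent with single-reference calibration;
multi-patch chart calibration and camera-RAW development are out of
scope.

The representation itself is a biologically inspired *visual
signature*, built in three stages.

**Channels.** The grayscale pathway uses only the luminance image
(ITU-R BT.601 weights, `L = 0.299 R + 0.587 G + 0.114 B` — the
classical choice for encoded video signals). The color pathway adds
eight *single-opponent* center-surround channels
(`compute_opponent_channels()`): each opponent pair — red/green,
yellow/blue (yellow = (R+G)/2), red/cyan (cyan = (G+B)/2) and the
achromatic white/black pair on luminance — is coded as a signed plane
`O = P − Q` and filtered with a unit-normalized difference of
Gaussians, `S = G(σ_c) * O − G(σ_s) * O`, with `σ_c = 1` px and
`σ_s = 3 σ_c` by default. Half-wave rectification splits S into the
two complementary non-negative channels of the pair (a positive
"firing rate", as in cortical single-opponent cells). Two properties
pin this formulation down: a uniform field of any color produces zero
response in all eight channels (both Gaussians integrate to one), and
the two channels of a pair are complementary (their pixelwise product
is zero) while jointly carrying |S|. A center-tuned-to-P minus
surround-tuned-to-Q formulation on *separate* planes would violate the
first property on any uniform non-gray field, and would make the
white/black pair vanish identically; the one-plane difference-of-
Gaussians is also how the published single-opponent descriptor this
stage follows operates. The opponency is modeled on the primate visual
system; whether a tetrachromatic receiver would segment the same
classes is an open biological question, not one the package answers.

**C1.** Every channel is convolved with a bank of Gabor filters — bar
detectors of the kind found in primary visual cortex — at 16 scales
(filter sizes 7, 9, ..., 37 px, per-scale wavelengths and effective
widths from the published HMAX defaults, aspect ratio 0.3) and 4
orientations (0°, 45°, 90°, 135°), taking the absolute response.
Filters are zero-meaned and L2-normalized, so responses are linear in
image contrast. Adjacent scale pairs are then max-pooled over scale and
over local neighborhoods (pool sizes 8, 10, ..., 22 C1 cells per band,
half-overlapping grids), giving 8 bands of shift- and scale-tolerant
oriented edge-energy maps (`compute_c1()`). All bank parameters are
exposed in `gabor_bank()`.

**C2 / signatures.** A dictionary of templates is sampled at random
(image, band, location) triples across the corpus, divided equally
among four spatial extents — 4, 8, 12, 16 C1 cells by default
(`sample_templates()`). Each image's signature is then the vector of
maximal similarities `exp(−d²/(2 σ_t²))` between each template and the
best-matching location across all bands (`compute_signature()`), with
`σ_t² = L`, the template's dimensionality, so similarities are
comparable across size classes. Signature coordinate *i* always refers
to template *i*; values lie in (0, 1], and an image that contributed a
template scores exactly 1 on it.

One deliberate deviation from a strict reading of the template
contract: a size class is sampled from, and matched against, *the
bands large enough to host it*, with an error only if no band
qualifies. Requiring every size class to fit the *coarsest* band would
make the default configuration unusable below roughly 200 px of input
(the coarsest band of a 128-px image is about 10 cells wide), i.e. on
exactly the desk-scale images the package defaults target.

Template sampling draws from *all* images by default, including any
later used as test items — the classical dictionary protocol, which is
mildly optimistic; pass `template_images` to
`build_signature_matrix()` to restrict sampling to training images.
Re-sampling templates inside each leave-one-out fold is not
implemented.

## Distinguishability

Two labeled classes are compared by the leave-one-out (LOO) success
rate of a linear soft-margin SVM (libsvm via e1071) with `C = 1` and
dual tolerance 1e-6 (`loo_success_rate()`): each sample in turn is
held out, the classifier is trained on the rest, and the held-out
sample's predicted label is compared with the truth. Features are
standardized per training fold inside the solver (libsvm's recommended
preprocessing). This matters at desk scale: the Gaussian similarity
compresses signature values toward 1, and without standardization a
`C = 1` classifier on such low-dynamic-range features underfits to the
majority-class bias even when the classes form cleanly separated
clusters. Standardization makes the analysis invariant to that overall
scale while preserving determinism, label symmetry and permutation
calibration. Decision values of exactly zero go to the
lexicographically first class name, so predictions are deterministic.

Significance comes from a label-permutation test
(`permutation_p_value()`): the labels are shuffled uniformly and the
*entire* LOO loop is recomputed per permutation — the exact reading of
permuting labels among all samples; no within-fold shortcut is offered,
because LOO predictions depend on the training labels and any shortcut
changes the statistic. The P-value uses the add-one estimator
`p = (1 + #{null ≥ observed}) / (m + 1)`, never zero and bounded below
by `1/(m+1)`. The full-scale protocol uses 10,000 permutations;
desk-scale analyses in the tests use 99–999.

With few samples per class in a high-dimensional signature space the
permutation null has a heavy upper tail: shuffled labels can reach a
perfect LOO rate by chance (at 5 + 5 samples this happens in a few
percent of shuffles), so the same success rate can carry very
different P-values at different group sizes, and P is not a monotone
function of the rate across pairs. The pairwise table therefore
reports the per-class sample sizes alongside every rate and P-value;
one unit test documents the tail explicitly.

`pairwise_distinguishability()` runs every (or a requested subset of)
class pair(s) and can flag pairs by Holm's sequential Bonferroni
procedure at a family-wise 0.05. `assign_unknowns()` implements the
unknown-group protocol: train once on two classes, assign each unknown,
report assignment fractions, and test whether the unknown *group* can
be separated from each training class at all (a large P meaning
statistical indistinguishability).

The support-vector count is logged on each `loo_result` for
comparability with full-scale analyses; it is descriptive, not a
constraint.

## Field statistics

`chi2_2x2()` is the uncorrected Pearson chi-square (equal to
`N(ad−bc)²` over the margin product); no Yates correction, because the
field values this mirrors (16.6 on the 11/36-vs-0/47 mate-guarding
table; 0.24 on the 5/12-vs-15/30 copulation table) are uncorrected
statistics — both verified in the tests. Fisher's exact test is
available behind a flag for small cells. `binomial_exact_test()`
reports exact binomial tails; note that for 9 wins in 11 trials at
p₀ = 0.5 the exact one-sided tail is 67/2048 ≈ 0.0327 (not 0.027 — a
printed value this quantity is sometimes confused with; the package
reports the exact tail). `logistic_fit_lr()` is plain
maximum-likelihood logistic regression (IRLS, deviance tolerance 1e-8)
with per-term likelihood-ratio χ² tests; quasi-separation raises an
explicit error naming the offending covariate. Random-effects /
GEE-style extensions are deliberately out of scope — an unstated
working-correlation structure cannot be replicated faithfully — and a
year term can instead be included as a fixed covariate.
`anova_tukey()` is one-way fixed-effects ANOVA with Tukey–Kramer HSD
(unequal group sizes are the norm in field data).

## The synthetic generator

`generate_pattern_image()` renders an elliptical body (aspect 1.8 by
default) on a neutral ground with the three axes that define pattern
classes in this setting — base color, stripes, blotches — plus a
brightness multiplier (a "brighter version" of a pattern is a real
class distinction). A white strip along the top edge and a global
illumination factor (0.85) force every pipeline run through the
calibration stage. Noise enters as a per-image color cast (hue jitter),
stripe/blotch placement jitter, and iid pixel noise; the defaults
(0.02 each) are documented as arbitrary — no quantitative description
of within-class variability exists to calibrate them against — and
were chosen once so that distinct default classes are separable and
identical specs are not.

`blend_specs()` gives the *separation dial*: every numeric spec
parameter is moved toward the across-class mean,
`mean + separation × (spec − mean)`. Separation 0 collapses all
classes onto one spec — the null fixture, whose labels carry no visual
information; separation above 1 exaggerates differences.
`matched_luminance_color()` constructs hue pairs with exactly equal
BT.601 luminance, the fixture behind the key property: the grayscale
pathway is blind to constant-luminance hue rotation (equal signatures
to machine precision) while the color pathway separates the same pair
— which is what makes the paired color/grayscale analysis informative
about whether classes differ in pattern or only in color.

`generate_metadata()` emulates capture records: month uniform on
5–10, SVL truncated-normal (mean 10 cm, sd 2, bounds 5–16 cm), and
brown-vs-green color drawn from
`P(brown) = plogis(−0.23 + 0.416·month − 0.289·SVL)`. The two slopes
encode the seasonal increase in brown coloration and its decrease with
body size; the intercept is set so mean log-odds are near zero (about
half the records brown) at the covariate means, which keeps the
recovery simulations well-conditioned. Months are coded as integers
and SVL in cm; the recovery tests are internally consistent under that
convention (the coding that produced any particular published
coefficient magnitude is generally not recoverable from a paper, so
consistency, not coding, is the testable property).

What the generator does *not* emulate: real body shape and texture,
specular highlights, cast shadows, background clutter, viewpoint and
pose variation, or occlusion. Passing tests therefore show the
pipeline is correct and calibrated on images with controllable
class structure — not that any particular real-world class pair is
distinguishable; that conclusion always requires the real photographs.

## Numerical choices and problem sizes

- Determinism: every stochastic entry point takes a seed, isolates the
  RNG (saving and restoring the caller's stream), and derives
  sub-stream seeds arithmetically, so any stage can be reproduced
  independently.
- Solver: libsvm, linear kernel, `C = 1`, tolerance 1e-6; ties at
  decision value 0 break to the lexicographically first class.
- Logistic fits: IRLS with deviance tolerance 1e-8, max 100
  iterations.
- Degenerate inputs fail fast with specific messages: empty or
  out-of-bounds rectangles, all-zero calibration references, images
  smaller than the largest Gabor filter, single-class label vectors,
  classes with fewer than two members, fewer than 99 permutations,
  rank-deficient or separated logistic designs.
- Test-suite problem sizes (chosen for minutes-scale runs on one CPU;
  the full-scale protocol scales every one of them up): positive
  control at 128×128 px, 10 images/class, 200 templates, 199
  permutations; null calibration at 64×64 px grayscale, 100 templates
  (size classes 2/4/6/8), 20 replicate datasets, 99 permutations;
  classifier-level type-I simulation at 40 datasets × 99 permutations;
  coefficient recovery at 200 replicates of n = 148.

## A worked example

```{r, eval = FALSE}
library(pattsig)

# two distinct classes, end to end
ds <- synthetic_signature_run(default_pattern_specs()[c("A", "F")],
                              n_per_class = 10, size = c(128, 128),
                              separation = 2, mode = "color", seed = 2024,
                              n_templates = 200)
permutation_p_value(ds, n_permutations = 199, seed = 5)

# seasonal color-change statistics on synthetic capture records
md <- generate_metadata(n = 148, seed = 1)
md$brown <- as.integer(md$color == "brown")
logistic_fit_lr(md, "brown", c("month", "svl"))
```

## Known limitations

- The calibration model is a per-channel gain on encoded sRGB values;
  it cannot correct illuminant color shifts that are not multiplicative
  in that encoding, and the editing-program operation it stands in for
  is not documented anywhere, so exact agreement with any historical
  calibration is not claimed.
- Desk-scale defaults (≤ 256 px, 200 templates) trade accuracy for
  runtime; full-scale runs (full resolution, 1000 templates, 10,000
  permutations) use the same code paths via configuration but are not
  exercised by the test suite.
- The grayscale pathway's hue invariance holds for *constant-luminance*
  changes only; any real hue change that alters luminance leaks into
  the pattern channel.
- Reference success rates obtained on a particular field-photograph
  corpus are reproducible only with that corpus
  (`analyze_image_corpus()` is the entry point for users who have
  one); the package's tests establish correctness and calibration on
  synthetic data.
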