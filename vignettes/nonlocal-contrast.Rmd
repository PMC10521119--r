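---
title: "Nonlocal contrast: the second-order operator, stimulus synthesis, and the statistics layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlocal contrast: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlcontrast)
```

## The model

Early visual cortex measures luminance gradients with band-pass ("first-order")
filters. A second stage — the second-order or filter–rectify–filter (FRF)
mechanisms — pools rectified first-order outputs over a larger region and
responds not to luminance itself but to spatial *modulations* of local
contrast. Such units are silent on homogeneous textures and fire where the
texture's contrast, orientation or spatial-frequency content changes across
space. `nlcontrast` implements an image-computable operator of this kind for
contrast modulation, uses it to rank image regions by how much their contrast
energy stands out from their surround, and resynthesizes images from the
selected regions through Gaussian apertures (a deterministic variant of the
"bubbles" technique, with apertures at model-chosen rather than random
positions). The accompanying statistics layer analyzes the between-subjects
recognition-accuracy experiments such stimuli are built for.

### The operator

For a square luminance image of side $S$ pixels, the operator bank is derived
from three construction rules:

* the coarsest center diameter is half the canvas, $d_1 = S/2$, and each
  further scale halves it (a 1-octave size step): $d_k = S/2^k$;
* the center band-pass peak is always **4 cycles per center diameter**,
  $f_k = 4S/d_k$ cycles per image (cpi), with a **1-octave** bandwidth —
  a fixed ratio between first- and second-stage tuning that makes the
  description scale-invariant;
* the number of selected windows per scale satisfies $N_k d_k = S$, so the
  summed diameters of the selected areas equal the image diameter:
  $N_k = 2, 4, 8, 16$.

For the default 256-px canvas this gives $d = 128, 64, 32, 16$ px and
$f = 8, 16, 32, 64$ cpi. The finest band must stay below Nyquist, which is why
256 px is the default working resolution for an 8-degree image; on a 128-px
canvas only three scales are realizable and `operator_scales(128, 3)` should
be used.

At scale $k$ and position $p$ the operator computes

$$ A_k(p) \;=\; \underbrace{\left\langle \big(B_{f_k} I\big)^2 \right\rangle_{\mathrm{disk}(p,\, d_k)}}_{\text{center band energy density}}
\;-\; \underbrace{\frac{1}{M}\sum_{b=1}^{M} \left\langle \big(B_{f_b} I\big)^2 \right\rangle_{\mathrm{annulus}(p)}}_{\text{surround power per octave}} $$

where $B_f$ is an isotropic log-Gaussian band-pass filter (unit peak gain at
$f$, amplitude FWHM of one octave, DC removed exactly), the rectifying
non-linearity is squaring (the energy model), the disk has diameter $d_k$, and
the annulus has inner radius $d_k/2$ and outer radius $3d_k/2$ — a ring whose
width equals the center diameter. The surround bank is octave-spaced from
2 cpi up to Nyquist ($M = 6$ bands at 256 px), standing in for the full range
of frequencies the observer can see. Both terms are per-pixel energy
*densities*: the annulus has eight times the disk's area, so raw totals would
not be comparable. With this normalization the two terms are equal in
expectation on any texture whose power per octave is spatially homogeneous
(natural images, with their $1/f$ amplitude spectra, are approximately such
textures), which is what makes the difference a detector of contrast
*modulation* rather than of spectral content.

All maps are computed in the frequency domain: one FFT of the reflect-padded
image feeds every band, each band is squared and convolved with a normalized
disk or annulus kernel, and the result is cropped back. The test suite proves
the convolution path equal to direct per-pixel disk/annulus averaging at
random probe points to ~1e-12 relative.

### Numerical and design choices

* **Filter family.** An isotropic log-Gaussian radial amplitude transfer
  (log-Gabor-like). Its symmetry in log-frequency matches octave-bandwidth
  conventions, and it has no DC leak by construction. Bandwidth is defined as
  the amplitude full width at half maximum: a grating half an octave off-peak
  passes at half amplitude (quarter power).
* **Border policy.** Reflective padding by $\lceil 1.5 d_k\rceil$ so the
  surround annulus always has data; extremum search is restricted to a margin
  of $d_k/2$, which keeps the center disk fully inside the original canvas.
  Restricting instead to the full operator footprint ($3d_k/2$) would leave
  an empty valid region at the coarsest scale (margin 192 on a 256 canvas),
  making the 2-window coarse scale unusable, so the center-disk criterion is
  used; the surround beyond the canvas relies on the reflection.
* **Surround range.** 2 cpi to Nyquist, octave-spaced, configurable
  (`band_lo`, `band_hi`). Band peaks at or above Nyquist are rejected.
* **Extremum selection.** Strict local extrema over 8-connected
  neighborhoods; equal-valued plateaus whose whole border is lower (higher)
  reduce to their centroid; ties break in row-major scan order, so selection
  is deterministic given the map. Greedy selection in amplitude order with a
  minimum center separation of $d_k$ (tangent windows allowed). If the map
  lacks enough separated extrema the set is returned short, with a warning.
* **Medium class.** "Medium" points are defined by amplitude-rank pairing:
  the rank-$j$ target is the midpoint of the $j$-th selected maximum and
  minimum amplitudes, and the chosen pixel is the valid-region position whose
  amplitude is nearest the target, under the same separation constraint.
  Pairing by spatial proximity instead would be a different reading of
  "between the closest minimums and maximums"; amplitude pairing was chosen
  because the stimulus classes are defined by amplitude.
* **Apertures.** Radial Gaussians with FWHM equal to $d_k$, so every window
  transmits four cycles of its scale's band; weight 1 at the center, 0.5 at
  $d_k/2$, $2^{-4}$ at $d_k$. The profile is truncated where it falls below
  1% of peak (radius $\approx 1.29\,d_k$): windows then have compact support
  and the background of a synthesized stimulus is *exactly* uniform outside
  all windows. Overlapping windows blend by pointwise maximum of weights —
  summing would double contrast where windows overlap.
* **Calibration.** Images are normalized to mean luminance 35 cd/m² and RMS
  contrast 0.45 by an exact affine map. If the map would drive pixels
  negative, they are clipped; when clipping touches ≥ 1% of pixels a warning
  is raised and the normalization re-applied once post-clip. Deeply modulated
  synthetic textures routinely clip a percent or two — the warning is
  informative, not an error. Luminance is an abstract calibrated scale; no
  display gamma model is applied, because the operator depends only on
  relative contrast.

## What the synthetic fixtures emulate — and what they do not

Every test input is generated in code with known ground truth:

* `make_modulated_texture()` multiplies a carrier (narrowband noise, a
  grating, or broadband noise with equal power per octave — the
  natural-image spectral profile) by $1 + m\,E(x)$ with a known envelope $E$
  (an offset raised-cosine bump, or a sinusoid) and depth $m \in [0,1]$. The
  envelope raster is returned, so localization and monotonicity are checked
  against construction, not against another model.
* `make_schematic_face()` places three high-contrast band-passed patches at
  eye and mouth positions on a faint oval and low-contrast broadband
  background — a caricature of where contrast-modulation maxima of real
  faces concentrate. Patch centers are the truth.
* `simulate_response_logs()` emulates the reference three-group
  between-subjects design: per observer a true accuracy is drawn from a
  Normal clamped to [0, 100] (default group means 5, 35, 61% for the min /
  med / max amplitude classes; group sizes 13, 12, 13), then 120 face-trial
  outcomes are drawn binomially; errors answer a wrong label or "don't know"
  with equal probability. "Don't know" is scored as incorrect throughout.

Passing tests on these fixtures show that the operator does what its
definition promises on signals with known envelopes and spectra. They do not
show that real photographs yield the same selected regions as the original
software, that the measured accuracy ordering transfers to human observers,
or that the schematic face is a substitute for face photographs — the
behavioral accuracies (5% → 61%) are a property of human observers viewing
photograph-derived stimuli and are not reproducible from a desk.

Two empirical notes from developing the fixtures. First, the operator's
response to *unmodulated* broadband noise is not numerically zero: the center
pools roughly 50 independent coherence cells (4 cycles per diameter at a
1-octave band — a scale-invariant count), so band-energy estimates fluctuate
by ~20% around their mean. The zero-response property is therefore stated
against the peak response of a fully modulated twin of the same carrier (the
operator's response to full modulation), where the baseline sits near 2%.
Second, the contrast ordering of synthesized stimulus classes (max > med >
min in RMS contrast) is guaranteed only when the source image's local
contrast actually spans a range; minimum-*amplitude* windows of a
contrast-homogeneous image still transmit carrier contrast, because minimum
amplitude marks center-below-surround, not absence of contrast.

## The statistics layer

`nl_anova(data, value, group)` reproduces the full report for a one-way
between-subjects accuracy comparison: Levene's test (mean- or
median-centered, via `car::leveneTest()`), the classical ANOVA
(`stats::aov()`), the Brown–Forsythe statistic
$F^* = SS_b \big/ \sum_i (1 - n_i/N)s_i^2$ with Satterthwaite denominator df
(no installed implementation exists, so it is computed directly), the Welch
statistic (`stats::oneway.test()`), partial $\eta^2 = SS_b/(SS_b + SS_w)$ and
Cohen's $f = \sqrt{\eta^2/(1-\eta^2)}$, and Tukey post hocs
($SE = \sqrt{MS_w(1/n_a + 1/n_b)}$, $p$ from the studentized range) with
Bonferroni and Holm corrections of the raw pairwise $t$ p-values. Following
the convention of standard ANOVA reports, the corrected rows keep the
classical sums of squares and report $MS_w = SS_w/\mathrm{df}_2$ at the
corrected denominator df. `anova_from_sums()` and `posthoc_from_sums()`
rebuild all derived statistics from published summary numbers, for auditing
printed tables.

One identity often assumed of the corrections is worth stating precisely:
Brown–Forsythe reduces *exactly* to the classical $F$ whenever the group
sample variances are equal (any $n$), but Welch does not — its denominator
$1 + \tfrac{2(k-2)}{k^2-1}\Lambda$ exceeds 1 at any finite $n$ even under
perfect variance equality (about 3.6% at $n = 10, k = 3$) and converges to
the classical statistic only as $n \to \infty$. The tests check exactly that:
BF equality at small $n$, Welch agreement in the large-$n$ limit.

The generator's between-observer spread for the effect-size recovery suite,
`sigma = 18.6` percentage points, is derived, not asserted: it is the value
at which the clamped-Normal-plus-Binomial process at the default design
yields a median recovered partial $\eta^2$ of 0.634 (grid search, 2000
replicates per candidate). Clamping at 0 biases the lowest group's mean
upward by ~2.7 points at $\sigma = 12$; recovery checks account for this.

A second design note: the post hoc SEs of the reference report imply group
sizes (13, 12, 13) for (min, med, max), while its design text assigns 12
observers to the max-faces group. The package reproduces whichever mapping is
supplied; the default follows the SE-consistent one.

## Problem sizes

The standard canvas is 256 px (8 degrees), at which one amplitude map costs a
handful of FFTs on a ≤ 640² padded grid (~1 s). The property suites run 20
seeds of paired 256² maps for zero-response, 500 replicates for effect-size
recovery and 2000 for the Welch type-I calibration; unit tests use 128-px
canvases (the scheme is canvas-relative, so only runtime changes).

## Worked example

```{r example, eval = FALSE}
library(nlcontrast)

# a schematic face with known informative loci
face <- make_schematic_face(seed = 1)
img  <- face$image          # normalized to 35 cd/m2, RMS 0.45
maps <- multiscale_maps(img)

# select per-scale maxima and synthesize the max-amplitude stimulus
sets <- lapply(maps, select_extrema, polarity = "max")
stim <- synthesize(img, sets)
autoplot(maps$k2)

# the statistics layer on simulated response logs
logs <- simulate_response_logs(seed = 1)
fit  <- nl_anova(accuracy_table(logs), accuracy_pct, class)
tidy(fit)
glance(fit)
autoplot(fit)
```

## Known limitations

* No eccentricity weighting: all image positions are treated alike, as in
  the modeled mechanism bank.
* Contrast modulation only; orientation- and frequency-modulation
  second-order channels are out of scope.
* The window counts $N_k = S/d_k$ are a design convention (selected areas
  tile the image diameter), not an optimum; richer images than the fixtures
  may support more informative areas per scale.
* The surround's "entire visible range" is approximated by octave bands from
  2 cpi to Nyquist of the working canvas, not by a psychophysical CSF.
* Whether combined stimuli should be re-normalized to a common total
  contrast after blending is left to the user (`normalize_luminance()` on
  the result); the default preserves the windows' native contrast.
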