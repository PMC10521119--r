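# nlcontrast

An image-computable model of **second-order visual mechanisms** — the
filter–rectify–filter units that detect spatial modulations of local contrast
rather than luminance itself — together with the stimulus-synthesis and
statistics machinery of the psychophysical experiments such models feed.

The package is for visual neuroscientists and psychophysicists who want to

* compute **nonlocal contrast modulation amplitude maps** of face/object
  images at octave-spaced scales,
* select the regions of maximum, medium, and minimum modulation amplitude
  under non-overlap constraints,
* cut those regions through Gaussian apertures and recombine them into
  "bubbles"-style stimuli (with apertures at model-chosen, not random,
  positions), and
* analyze the resulting between-subjects accuracy data with the standard
  heterogeneity-corrected ANOVA battery.

## The model

For a square image of side *S* px, scale *k* uses a sliding center–surround
operator: center disk of diameter *d<sub>k</sub> = S/2<sup>k</sup>*, band-pass
peak *f<sub>k</sub> = 4S/d<sub>k</sub>* cycles/image (always 4 cycles per
center diameter, 1-octave log-Gaussian bandwidth), and a surround annulus of
ring width *d<sub>k</sub>*. The amplitude map is

> A<sub>k</sub>(p) = ⟨(B<sub>f<sub>k</sub></sub>I)²⟩<sub>disk(p)</sub> −
> (1/M) Σ<sub>b</sub> ⟨(B<sub>f<sub>b</sub></sub>I)²⟩<sub>annulus(p)</sub>

— center band-energy density minus octave-averaged surround power density,
both per pixel so the 8× area difference cancels. The operator is silent on
textures with spatially homogeneous per-octave power and responds where local
contrast stands out from its surround. Per scale, *N<sub>k</sub> = S/d<sub>k</sub>*
(= 2, 4, 8, 16) windows are selected so the summed window diameters tile the
image diameter; apertures are radial Gaussians with FWHM *d<sub>k</sub>*, so
every window transmits four cycles of its band.

The statistics layer mirrors a three-group between-subjects design: Levene's
test, classical / Brown–Forsythe / Welch one-way ANOVA, partial η² and
Cohen's *f*, Tukey–Bonferroni–Holm post hocs, and Clopper–Pearson binomial
intervals. `anova_from_sums()` / `posthoc_from_sums()` rebuild every derived
statistic from a published table's sums of squares, mean differences and SEs.

## Worked example

```r
library(nlcontrast)

face <- make_schematic_face(seed = 1)   # synthetic face-like fixture
img  <- face$image
img
#> <lum_image> 256 x 256 px, 8 deg, mean 35.02 cd/m2, RMS contrast 0.4485 (normalized)

maps <- multiscale_maps(img)            # amplitude maps at d = 128, 64, 32, 16 px
select_extrema(maps$k2, "max")          # 4 windows at the 16-cpi scale
#> <extrema_set> kind=max, 4 points (min_sep 64 px)
#> # A tibble: 4 × 3
#>       x     y amplitude
#>   <dbl> <dbl>     <dbl>
#> 1   158    97    239.
#> 2   129   184    157.
#> 3    88    94    118.
#> 4    36   221      6.41
```

The three strongest maxima sit on the right eye (158, 97), the mouth
(129, 184) and the left eye (88, 94) — the fixture's planted informative
loci; the fourth, far weaker one (amplitude 6.4 vs 118–239) is background.
`synthesize(img, sets)` then blends those regions through Gaussian apertures
onto the uniform 35-cd/m² background.

```r
logs <- simulate_response_logs(seed = 1)     # 3 groups, 13/12/13 observers
fit  <- nl_anova(accuracy_table(logs), accuracy_pct, class)
fit
#> One-way ANOVA with heterogeneity corrections
#>      correction ss_effect df1 ms_effect ss_resid     df2 ms_resid statistic
#>            none   28167.8   2   14083.9  10564.8 35.0000  301.853   46.6581
#>  brown_forsythe   28167.8   2   14083.9  10564.8 29.4724  358.466   46.1237
#>           welch   28167.8   2   14083.9  10564.8 21.1920  498.530   47.9826
#> ...
#> Levene (mean-centered): F(2, 35) = 1.769, p = 0.1854
```

Accuracy rises steeply with the amplitude class of the areas the stimulus was
built from (here η²ₚ = 0.73 for this simulated draw); `tidy(fit)`,
`glance(fit)` and `autoplot(fit)` give the table, the one-row summary, and a
group-means plot.

A thin command-line front end over the same functions lives at
`inst/cli/nlcontrast.R` (`map`, `extract`, `synthesize`, `stats`, `fixtures`
subcommands).

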