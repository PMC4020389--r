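# tdch — tongue image colour analysis with two-dimensional colour histograms

Traditional East Asian medicine reads the tongue as a diagnostic sign: a
pale tongue body or a widely spread coating is taken to indicate qi/blood
deficiency. `tdch` implements a quantitative pipeline for that reading from
ordinary digital tongue photographs. It is aimed at researchers analysing
tongue-image cohorts (e.g. comparing a symptomatic against a normal group)
and at anyone who needs a tested reference implementation of the
two-dimensional colour histogram (TDCH) feature extractor.

## The method

Each photograph passes through five stages:

1. **Colour space.** 8-bit sRGB pixels are converted to CIE 1976
   (L\*, a\*, b\*) under the standard sRGB transfer function and D65 white.
   a\* > 0 is red; tongue pallor shows up as low a\*.
2. **Segmentation.** The tongue region is delineated automatically with a
   polar edge map of L\* (radial directional derivative about a centre
   estimate) and a gradient-vector-flow (GVF) snake, with a manual
   add/remove merge step for difficult images.
3. **Exclusion.** Dark tongue-root pixels (L\* < 30, low illumination) and
   specular saliva highlights (L\* > 85) are removed from the mask; pixels
   at exactly 30 or 85 are retained.
4. **Colour correction.** A 12-patch colour checker in the frame calibrates
   the image: per coordinate, an affine map `ref = slope * measured +
   intercept` is fitted by least squares — L\* on the 6 achromatic patches,
   a\* and b\* on the 6 chromatic patches — and applied to every pixel.
5. **TDCH.** Valid pixels are binned on a 4 × 4 lattice over (L\*, a\*)
   with half-open bins `[L, L+5) × [a, a+6)`, lower bounds L\* ∈ {30, 35,
   40, 45} and a\* ∈ {6, 12, 18, 24}. Counts are normalised by the valid
   tongue area, seven bins become the analysis variables V1–V7, and
   `VR = V7/V3` indexes the red intensity of the tongue body (V7: bright
   intense red; V3: pale red).

Downstream, the package reproduces the accompanying statistical battery —
Lilliefors-corrected Kolmogorov–Smirnov and Shapiro–Wilk normality tests,
normality-routed Mann–Whitney U group comparison, one-sample t on paired
differences — and 10-fold stratified cross-validation of naive Bayes, KNN
and SVM classifiers on V1–V7.

Because no clinical images ship with the package, a synthetic module
generates tongue phantoms (elliptical body with a bin-mixture colour field,
coating patch, specular spots, dark root band, embedded checker, optional
affine device distortion) and cohort tables with known ground truth, so
every stage is testable end to end.

## Worked example

```r
library(tdch)

# a synthetic tongue photograph with artefacts, checker and device distortion
ph <- generate_tongue_image(tongue_phantom_spec(
  coating = TRUE, specular_frac = 0.05, root_frac = 0.10, checker = TRUE,
  distortion = list(slope = c(0.95, 0.9, 0.9), offset = c(3, 1, -1)),
  seed = 11))

res <- analyze_image(ph$image, checker_regions = ph$checker_regions)
res$variables
#> # A tibble: 1 × 8
#>      V1    V2     V3    V4    V5    V6    V7    VR
#>   <dbl> <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1     0     0 0.0291 0.237     0 0.594 0.140  4.82

tidy(res$correction)
#> # A tibble: 3 × 5
#>   coordinate slope intercept    rss n_patches
#>   <chr>      <dbl>     <dbl>  <dbl>     <int>
#> 1 L           1.05     -3.18 0.0158         6
#> 2 a           1.11     -1.04 0.195          6
#> 3 b           1.11      1.02 0.103          6
```

The fitted slopes/intercepts invert the simulated device distortion
(1/0.95 ≈ 1.05, −3/0.95 ≈ −3.16), V4 and V6 carry the coating and main
body area fractions, and `VR = V7/V3 ≈ 4.8` says this phantom's body is
dominated by the bright-red range. `res$exclusion_report` shows 5.9% of
mask pixels removed as specular highlights.

Cohort-level analysis chains the same way:

```r
cohort <- generate_cohort(cohort_spec(seed = 1))   # 402 normal vs 52 sleep-disorder
group_compare(cohort)
#> # A tibble: 7 × 7   (Mann-Whitney U per variable, median (IQR) per group)
#> 1 V1       mann_whitney     10569 0.896   ...
#> 2 V2       mann_whitney      8522 0.0302  ...
#> 5 V5       mann_whitney     14636 0.00000261 ...
classify_battery(cohort, seed = 1)
#> 1 naive_bayes    0.879
#> 2 knn            0.881
#> 3 svm            0.886
```

A thin command-line wrapper (`inst/cli/tdch.R`) exposes `analyze`,
`stats` and `simulate` subcommands over the same functions.

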