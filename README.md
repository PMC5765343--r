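# casaR

Computer-assisted sperm analysis (CASA) for high-speed grayscale microscopy
video, built around the motility phenotyping used in Drosophila
male-fertility studies: sperm are recorded at 300 frames/s (228 × 320
pixels, 1000 frames, 28 pixels per 10 μm), and each recording is reduced to
three motion parameters that can be compared across genotypes with
rank-based statistics.

**Who it is for.** Researchers quantifying flagellar motility — e.g. sperm
hyperactivation after transfer to the female reproductive tract — from
high-speed video, who need reproducible estimators, a validated synthetic
test bed, and the accompanying nonparametric statistics.

## The three motion parameters

- **Beat frequency (Hz)** — the zero-crossing frequency of the
  mean-centred pixel-intensity time series at a measurement point: a
  sinusoid crosses its mean twice per cycle, so crossings / (2 × duration)
  estimates *f*. The default estimator refines crossing times by linear
  interpolation, which is exact for a pure sinusoid.
- **Beat speed (μm/s)** — the mean absolute frame-to-frame displacement of
  the flagellum along a probe line perpendicular to its axis (kymograph
  sub-pixel peak tracking), calibrated by `10/px_per_10um` μm per pixel.
  For a midline point moving as `A sin(2πft)` the target value is `4Af`.
- **Intensity index (%)** — the whole-field motion statistic

  $$\mathrm{index} = \frac{1}{m(n-d)} \sum_{i=d+1}^{n} \sum_{j=1}^{m}
  \frac{|p_{ji} - p_{j,i-d}|}{g} \times 100,$$

  the mean absolute lag-*d* brightness difference over all *m* pixels and
  all valid frame pairs, normalised by the brightness depth *g* = 256.

A deterministic synthetic-video generator (`generate_video()`) renders a
travelling sinusoidal wave `y(s,t) = A(s) sin(2πft − 2πs/λ + φ)` with a
Gaussian point-spread function and known ground truth, so every estimator
has an analytic target. The statistical battery provides exact
Wilcoxon–Mann–Whitney tests from the combinatorial null distribution of U,
tie-corrected Kruskal–Wallis, Dunn's post hoc comparisons with a compact
letter display, Bonferroni/Holm corrections, chi-square contingency tests,
and sperm-storage retention arithmetic.

## Worked example

```r
library(casaR)

model  <- flagellum_model(beat_frequency_hz = 15, amplitude_um = 5, noise_sd = 2)
config <- acquisition_config(n_frames = 600)
sim    <- generate_video(model, config)

points <- default_measurement_points(model, config)
motion_report(sim$stack, points, probe_length_px = 81)
#> Sperm motion parameters
#>  point_id beat_frequency_hz beat_speed_um_s
#>        p1             15.12           297.2
#>        p2             15.12           299.6
#>        p3             14.88           300.3
#>        p4             15.12           299.7
#>        p5             15.12           297.0
#>      mean             15.07           298.8
#> SE of mean: beat frequency 0.04683 Hz, beat speed 0.6894 um/s
#> Intensity index: 1.586 %
```

The true beat frequency is 15 Hz and the true mean lateral speed is
`4Af = 4 × 5 × 15 = 300` μm/s; the five measurement points recover both to
well under 1%. The intensity index is low because a single beating
flagellum moves only a small fraction of the 72,960-pixel field.

Comparing stored-sperm counts between two groups of five females:

```r
mann_whitney_exact(c(620, 590, 655, 640, 610), c(35, 50, 28, 44, 61))
#> W = 25, p = 0.0079365 (exact)
#> method: exact (no ties, count recursion)

proportion(64, 358)          # fertilised eggs
#> 17.9% (64/358), 95% CI [14.3, 22.2] (wilson)

format_percent(percent_decrease(437.1, 275.1))   # stored sperm, 1 h -> 24 h
#> [1] "37.1"
```

`W = 25` is the largest attainable U at n = 5 + 5, so the two-sided exact p
is `2/252`; the storage decrease says 37.1% of the sperm stored at 1 h are
gone by 24 h.

A thin command-line front end wraps the same functions
(`inst/cli/casa.R`; subcommands `simulate`, `measure`, `stats`,
`fertility`).

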