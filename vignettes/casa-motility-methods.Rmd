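---
title: "Quantifying sperm flagellar motility from high-speed video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sperm flagellar motility from high-speed video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casaR)
```

## The measurement problem

Drosophila sperm become hyperactivated after transfer to the female
reproductive tract: their flagellar beating grows faster and more vigorous
before they enter the storage organs (the seminal receptacle and the paired
spermathecae). Comparing motility across genotypes therefore means turning a
high-speed grayscale recording — here 228 × 320 pixel frames at 300
frames/s, 1000 frames per recording, with 28 pixels spanning 10 μm — into a
few numbers that can be ranked across groups. casaR implements three such
parameters, the synthetic recordings used to validate their estimators, and
the nonparametric testing battery used to compare them.

### Beat frequency (Hz)

At a measurement point near the flagellum the pixel intensity rises and
falls once per beat cycle. `beat_frequency()` takes the per-frame mean
intensity over a small window (`extract_series()`), smooths it with a short
centred moving average (default 3 frames — just enough to suppress 8-bit
quantization chatter, which would otherwise inflate the crossing count),
subtracts the mean (or median), and counts sign changes; a zero-valued
centred sample inherits the previous sign so a plateau cannot be counted
twice. A sinusoid crosses its mean twice per cycle, so the crossing count
estimates 2 × frequency × duration.

Two conversions from crossings to Hz are provided. The plain rate,
`crossings / (2 × duration)`, is exact to within one crossing only when the
crossings are evenly spaced; at a point offset from the centreline the
intensity signal is a periodic *pulse train* (the flagellum sweeps past once
per cycle), and the partial pulses clipped at the window boundaries can
shift the count by two crossings, i.e. 0.3 Hz at the default 3.3-s duration.
The default `method = "refined"` therefore locates crossing times by linear
interpolation and uses `(crossings − 1) / (2 × (t_last − t_first))`, the
standard refined zero-crossing period estimator: it is exact for a pure
sinusoid, insensitive to boundary clipping, and agrees with the plain rate
within `1/(2 × duration)`. On the noise-free synthetic sweep below it
recovers 5–25 Hz within 0.09 Hz at every default measurement point.

### Beat speed (μm/s)

"Tail beat speed at the point of focus" is realised measurably as the mean
lateral speed of the flagellum where it crosses a fixed probe line.
`kymograph()` samples the intensity along a short probe perpendicular to the
flagellum axis in every frame (bilinear interpolation off-grid);
`beat_speed()` tracks the sub-pixel peak of each profile and reports the
mean absolute frame-to-frame displacement, scaled by `fps × 10/px_per_10um`.
For a midline point moving as `A sin(2πft)` the mean absolute lateral speed
is `4Af`, which is the analytic target used throughout the tests; the
discrete-time estimate is biased low only by the factor
`sin(πf/fps)/(πf/fps)` (≈ 0.4% at 15 Hz and 300 fps).

Sub-pixel localisation uses parabolic interpolation around the profile
argmax, applied to `log(intensity − baseline)` when the three bracketing
values allow it — for a Gaussian-profiled curve the log-parabola is exact,
while a parabola on raw intensities carries a small systematic bias — and
falls back to the raw-intensity parabola otherwise. Frames whose profile
never exceeds `background + 3·SD` (median and MAD of the whole kymograph)
are treated as untracked; if more than half the frames are untracked the
input is rejected as untrackable rather than silently averaged.

### Intensity index (%)

The whole-field motion index is the mean absolute lag-`d` pixel brightness
difference, normalised by the brightness depth `g = 256` and expressed as a
percentage:

$$\mathrm{index} = \frac{1}{m(n-d)} \sum_{i=d+1}^{n} \sum_{j=1}^{m}
\frac{|p_{ji} - p_{j,i-d}|}{g} \times 100$$

with `n` frames and `m = 72,960` pixels per frame at the default geometry.
It is bounded by `100·(g−1)/g = 99.609375` (attained by a full-field 0/255
flicker at `d = 1`), is zero exactly for a lag-`d`-static stack, and scales
linearly with a pre-clipping scaling of the pixel differences. The lag
defaults to `d = 1`, the finest temporal resolution at 300 frames/s and the
most sensitive choice; it is exposed as a parameter because the index is not
comparable across different lags. The implementation is vectorised per frame
pair (constant memory in `n`) and is tested for *exact* equality against a
literal triple-loop transcription of the formula on random stacks.

## The synthetic recording generator

No raw recordings accompany the published measurements, so estimator
validation rests on `generate_video()`: a travelling sinusoidal wave on a
straight centreline,

$$y(s, t) = A(s)\,\sin(2\pi f t - 2\pi s/\lambda + \phi),$$

rendered as a bright curve with a Gaussian cross-section (width
`psf_sigma_px`, hard support cutoff at 4σ) plus a Gaussian-blurred disc for
the head, on a uniform background, with optional additive i.i.d. Gaussian
noise applied before clipping to [0, 255] and round-half-up quantization.
The rendering evaluates the perpendicular-distance Gaussian profile
analytically on the band of pixels the wave can reach (the limit of
depositing a Gaussian kernel along a densely sampled polyline, but exactly
consistent with the analytic midline and fully vectorised); the lateral
coordinate is corrected by the local slope so the profile width is measured
perpendicular to the curve. The wave is parametrised by the axial
coordinate, a standard small-amplitude approximation to arc length.

Conventions: 1-based (row, col) pixel indices with the origin at the
top-left and rows increasing downward (the R imaging convention); frame `k`
depicts `t = (k − 1)/fps` exactly, with no exposure integration. Frame `k`
with noise depends only on `(model, seed, k)`, so single frames and whole
stacks are bit-reproducible.

Defaults emulate the study's acquisition (228 × 320 px, 300 fps, 1000
frames, 28 px/10 μm) around a flagellum chosen to be realistic at that
magnification: a 60 μm visible segment, 5 μm amplitude, 40 μm wavelength,
10 Hz beat, peak brightness 200 on background 20, PSF σ = 1.2 px, and mild
camera noise (SD 2 gray levels; validation suites set `noise_sd = 0` where a
noise-free target is asserted). `beat_frequency_hz` must stay below the
Nyquist limit `fps/2` by construction.

What the generator does *not* emulate — and what passing its recovery suites
therefore does not demonstrate about real recordings: curved or precessing
centrelines, waveform asymmetry and harmonics of real flagellar bending,
multiple overlapping sperm, focus drift, illumination flicker, and motion
blur within an exposure. The recovery suites validate the *estimators*
(geometry, calibration, sub-pixel tracking, crossing counting), not the
biology.

`default_measurement_points()` places five points at axial fractions 0.15,
0.3, 0.5, 0.7 and 0.85, laterally offset to the local peak excursion: at
that offset the passing flagellum produces one intensity burst per cycle, so
the zero-crossing count maps directly to the beat frequency. (A point on the
centreline sees the flagellum twice per cycle and would measure 2f — the
classic frequency-doubling pitfall of point-intensity methods.)

## The statistical battery

All group comparisons are rank-based, mirroring the published analysis of
motility and storage-count data.

- `exact_u_distribution()` builds the exact null pmf of the Mann-Whitney U
  by the count recursion (a subset rank-sum dynamic programme), capped by
  default at `n1·n2 ≤ 400`; it is tested for exact equality against complete
  enumeration of all label assignments up to `n1, n2 ≤ 7`.
- `mann_whitney_exact()` reports the first-group U (midrank rank sum minus
  `n1(n1+1)/2`) — the convention consistent with every published (W, n, p)
  triple — and a two-sided p equal to twice the smaller tail, capped at 1.
  With ties it enumerates all `choose(N, n1)` relabelings of the observed
  pooled values when feasible (≤ 2·10⁶), otherwise falls back to seeded
  Monte-Carlo permutation flagged `exact = FALSE`. Tie-affected p-values
  depend on the tie pattern of the raw data, which is why published entries
  with half-integer W cannot be reproduced from the statistic alone.
- `kruskal_wallis()` is the midrank H with tie-correction divisor
  `1 − Σ(t³−t)/(N³−N)` (delegated to `stats::kruskal.test()`, with the
  all-values-identical degenerate case defined as H = 0, p = 1); the test
  suite recomputes the literal formula as an independent oracle.
- `dunn_posthoc()` implements Dunn's z for mean-rank differences with the
  tie-corrected variance, two-sided normal p-values, and optional
  Bonferroni/Holm adjustment. The default is unadjusted comparisons at
  α = 0.05, making the multiplicity decision explicit rather than implied.
  Note that with four groups and unadjusted tests, the family-wise false
  positive rate across the six pairs is far above 5%; the power property in
  the test suite (two well-separated pairs flagged exactly) accordingly uses
  Holm.
- `compact_letter_display()` uses insert-and-absorb: groups share a letter
  iff their comparison is non-significant, letters assigned `a, b, c, …` in
  group order; it reproduces the published a / ab / ab / b layout from a
  significance matrix in which only the extreme pair differs.
- `chisq_contingency()` is Pearson's chi-square without continuity
  correction, and `adjust_pvalues()` wraps Bonferroni and Holm (sequential
  Bonferroni) via `stats::p.adjust()`.

A calibration property completes the battery: over 2000 null replicates at
n = 5 + 5 the exact test rejects at nominal 5% in ~3.2% of cases — exact
rank tests are conservative because 0.05 is not an attainable level of the
discrete null (the nearest attainable levels at these sizes are 8/252 below
and beyond it).

## Fertility and storage arithmetic

`percent_decrease()` / `percent_retained()` (complementary by construction),
`proportion()` (Wilson score interval by default — well-behaved at the small
counts typical of dissection data — with a Clopper-Pearson option), and
`storage_table()` (order-invariant wide summary with per-organ decreases)
reproduce the published retention percentages from the published mean
counts: 437.1 → 275.1 is a 37.1% decrease, 31.1 → 3.7 is 88.1% (displayed
as "88" in the source, which truncates that one value), 194.5 → 178.6 is
8.2%, 7.2 → 5.3 is 26.4%, and 64 of 358 eggs is 17.9%. Display rounding is
round-half-up at one decimal with trailing-zero trimming
(`format_percent()`), and is deliberately separated from the full-precision
values carried in code.

## Numerical choices and degenerate inputs

- Quantization is round-half-up after clipping; all 8-bit I/O round-trips
  bit-exactly (TIFF via deflate, PNG frame directories equivalently).
- Calibration (`fps`, `px_per_10um`, `bit_depth`) lives in a plain-text YAML
  sidecar, never in image headers, because TIFF resolution tags are
  unreliable across writers; microns are `px × 10 / px_per_10um`.
- A constant intensity series has beat frequency 0 (not an error); a
  background-only kymograph is an error ("untrackable"), not a zero.
- Measurement windows and probes must lie wholly inside the frame; mixed
  frame shapes name the offending frame; RGB and (unflagged) 16-bit input
  are rejected rather than silently converted.
- `exact_u_distribution()` counts are exact in double precision up to the
  default cap (the largest count, `C(40, 20) ≈ 1.4·10¹¹`, is far below
  2⁵³).

## Problem sizes used in the validation suites

The frequency-recovery sweep renders five full-scale recordings (default
acquisition, f ∈ {5, 10, 15, 20, 25} Hz, noise-free) and the speed sweep six
(A ∈ {2, 5, 8} μm × f ∈ {5, 15} Hz); unit tests use a compact 64 × 96 px
geometry that preserves all invariants. Null calibration uses 2000
replicates; enumeration oracles run to `n1 = n2 = 7` (3432 arrangements) and
50 random stacks for the intensity-index identity.

## Known limitations

- The synthetic wave is a pure travelling sinusoid (optionally tapered);
  real flagellar waveforms are asymmetric and curved, so absolute recovered
  values on real data inherit none of the suite's guarantees beyond the
  calibration identities.
- The intensity index depends on the unpublished lag `d`; cross-study
  comparisons require fixing it (default `d = 1`).
- Tie-affected exact p-values are data-dependent; only the statistic and
  the tie-handling policy, not published tied p-values, can be validated.
- Beat speed assumes a single trackable flagellum crossing the probe;
  overlapping sperm violate the single-peak model.
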