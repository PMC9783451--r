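---
title: "Methods: from wing landmarks and song spectra to morphs and decoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wing landmarks and song spectra to morphs and decoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphsong)
```

`morphsong` analyses paired observations of cricket wing morphology (form)
and song structure (function) to ask whether the morphology-to-signal
mapping is shared across male morphs or has been rewired during signal
diversification. This vignette explains the models and procedures, the
parameters that matter, the synthetic cohort generator, and the numerical
and design choices a maintainer should know about.

## Song features

A recording is reduced to nine characteristics. The spectral estimate is a
Welch-averaged periodogram: Hann-tapered segments (default window 256
samples, matching common plot-spectrum practice; 50% overlap), averaged and
normalised so that total spectral power equals the waveform's mean square
(taper-corrected). Bin spacing is `sample_rate / window_size`, so window
256 at 44.1 kHz resolves ~172 Hz; a larger window (4096) is used where
carrier recovery is verified.

The features are:

1. **Dominant frequency** — the bin with maximal power. Ties break to the
   lowest frequency (a documented, deterministic rule).
2. **Amplitude** — `20·log10(RMS / reference)`, with reference 1 (dB full
   scale) by default; supply a calibration constant for SPL.
3–8. **Band-relative amplitudes A–F** — spectral power integrated over six
   contiguous half-open bands, converted to per-band RMS amplitudes, and
   normalised by the sum of the six.
9. **Frequency evenness** — the negated standard deviation (sample, n−1
   denominator; configurable to population) of the six proportions: 0 for
   a perfectly even spectrum, −√(1/6) ≈ −0.408 when all energy falls in
   one band. Broadband (purring-like) songs score near 0.

The band edges are configuration, not constants of the method: the hearing
system this analysis targets has receptor clusters producing peaks and
valleys in sensitivity, and published edge values are not available. The
defaults (0–3.5, 3.5–6.5, 6.5–9.5, 9.5–12.5, 12.5–16, 16–20 kHz) place the
ancestral carrier (~4.8 kHz, and its slightly higher courtship variant)
inside the second band rather than on an edge — a band boundary sitting on
a carrier would split biologically identical songs into different band
profiles — and reserve a high band for the ultrasound-sensitive range.
Every feature table records the band table used.

Relative amplitudes are invariant to global waveform scaling, and
amplitude shifts by exactly `20·log10(scale)`; these invariances are
tested.

## Wing morphometrics

Fourteen landmarks per right wing (tpsDIG convention: origin bottom-left,
y upward; a flip option covers image-coordinate digitizers). Two structure
measures are computed on **calibrated raw coordinates** because they are
physical sizes that Procrustes scaling would destroy: harp width, the
x-axis distance between landmarks 5 and 14; and mirror size, the centroid
size of the mirror-perimeter landmarks 6–11, reported only when the mirror
is present.

Shape analysis uses generalized Procrustes alignment: configurations are
centred, scaled to unit centroid size, and iteratively rotated
(least-squares, proper rotations) to the running mean shape until the mean
changes by less than `tol` (default 1e-10, cap 100 iterations; hitting the
cap is reported, not hidden). Aligned coordinates feed a covariance-based
PCA whose axis signs follow a fixed convention (largest-magnitude loading
positive), making scores independent of specimen order.

## The trait matrix and morph discovery

The clustering set contains the individuals with complete calling-song,
courtship-song and wing data. The default trait list has 33 entries:
9 + 9 song characteristics and 15 continuous wing variables (harp width,
mirror size, 13 shape PCs). The categorical structure scores (scraper,
mirror, file gaps) are treated as diagnostic information for
classification rather than clustering variables: they are scored
presence/absence data collected alongside the landmark morphometrics, and
a 0/1 column z-scored against a small minority class acts as an extreme
outlier dimension that can dominate Euclidean distances. Users who want
them in the matrix can pass an explicit `traits` vector (they are encoded
0/1 before scaling). A mirror that is absent is a real phenotype, not
missing data, so `mirror_size` enters the matrix as 0 for mirror-less
wings; otherwise every purring male would be lost to complete-case
filtering.

Each trait is z-scored; zero-variance traits are an error naming the
trait. Clustering is agglomerative under the Ward.D2 criterion
(Lance–Williams update on squared dissimilarities, heights on the distance
scale), implemented with a deterministic tie rule (lowest row/column pair)
and verified against the standard implementation to 1e-8.

The number of morphs is chosen by the gap statistic: within-cluster
dispersion `W_k` (half the mean within-cluster pairwise distance sum) from
hierarchy cuts, compared to `B` reference datasets drawn uniformly in a
null box. Two null spaces are available. The default, `"scaledPCA"`, draws
uniformly over the ranges of the principal axes of the centred data and
rotates back, so the null box follows the data cloud's orientation; the
simpler `"original"` option uses each observed trait range. The default
matches the behaviour of the widely used gap implementations this analysis
descends from, and matters in practice: in 33 correlated dimensions the
raw-range box is far larger than the data cloud, reference dispersion
declines too slowly with k, and the gap curve rises monotonically —
inflating the selected k even on data whose three-cluster cuts are
perfect. The selection rule is `firstSEmax` (find the first local maximum
of the gap curve, then take the smallest k within one standard error of
it); `globalmax` and the original one-standard-error rule are available.
Reference draws are seeded and isolated from the caller's RNG state, so
gap results are reproducible and row-order invariant.

Individuals with only one song type (the larger field sample) are
classified by nearest centroid on z-scored diagnostic traits — mirror
presence, harp width, amplitude, frequency evenness, dominant frequency,
file gaps by default — an explicit operationalisation of classifying new
individuals by the phenotypes that defined the clusters. Ties go to the
first morph with a warning.

## Form–function statistics

Within each morph, wing structures are correlated with calling-song
characteristics: product-moment r with the asymptotic t approximation
(`t = r·√((n−2)/(1−r²))`, two-sided). Cells with fewer than 4 complete
pairs or without within-morph variation are reported as NA **with a
reason** rather than erroring — e.g. mirror size cannot correlate with
anything in purring males because none have mirrors; that NA is itself a
finding. Raw p-values are reported by default (the grid is descriptive);
Holm adjustment is a flag.

The decoupling summary flags a trait pair when its set of significantly
correlated morphs differs across morphs — some but not all morphs
significant, or significant with opposite signs. Under form–function
continuity all morphs share the same significant relationships with the
same signs and nothing is flagged.

Supporting tests are implemented from their defining formulas and verified
against independent references to 1e-8: Welch's t with
Welch–Satterthwaite fractional df; Levene's test with median centering by
default (the Brown–Forsythe variant, the common default in R analyses;
mean centering available) — note the median-centred statistic is slightly
conservative for very small groups, which is inherent to the statistic;
and MANOVA on PC1–2 with Pillai's trace (Wilks available — the choice is
exposed because published F values do not always name the statistic).

## Receiver models

Detectability uses an audiogram-style threshold curve supplied as
(frequency, required dB SPL) nodes, interpolated **linearly in log
frequency** (the audiogram convention) and never extrapolated: queries
outside the node range are errors, because the curve is only known where
it was measured. The margin of a song is its SPL minus the threshold at
its dominant frequency; `threshold_difference()` gives the extra
amplitude a song at one frequency needs relative to another. With any
plausible curve shape rising above ~5 kHz, scraperless purring songs
(median 13.6 kHz) need substantially louder output than scraper-bearing
ones (7.6 kHz); the package asserts the ordering, not a specific dB value,
because that value depends entirely on the user's digitised curve.

Phonotaxis outcomes are modelled with Firth's penalized logistic
regression: Newton iteration on the hat-adjusted score
`U*(β) = X'(y − p + h(½ − p))` maximising `ℓ(β) + ½·log det I(β)`, with
step-halving and convergence when the modified score norm falls below
1e-6. The Jeffreys penalty keeps estimates finite under complete
separation (e.g. no responses to a control stimulus). Fits are verified
against an independent direct maximization of the penalized likelihood.
Pairwise stimulus contrasts are Wald tests on the penalized fit with
optional Holm adjustment. A random-effect model for repeated measures per
female is deliberately out of scope; the fixed-effect contrasts answer
the stimulus-ordering question the trials are designed for, and the
penalized fit is exactly what the separation in such data requires.

## The synthetic cohort generator

The generator stands in for field data and defines the conditions the
tests and acceptance checks run under. It is phenomenological, not
biomechanical: a song is a carrier sinusoid shaped by a raised-cosine
pulse-train envelope (default 30 pulses/s; file-gap archetypes interrupt
each pulse with two short envelope discontinuities), mixed with
band-limited (2–20 kHz) noise at a drawn power fraction, scaled to a drawn
RMS level, plus a broadband ambient recording floor at −45 dBFS — field
recordings of the quietest songs sit within a few dB of background noise,
and that floor is what makes quiet-song spectral features realistically
noisy. A wing is the archetype's landmark template with landmarks 5/14
displaced to hit the drawn harp width, mirror landmarks scaled to the
drawn mirror size (or collapsed to a vestigial remnant when absent), and
isotropic Gaussian landmark noise (default SD 0.1 mm, ~2% of wing span —
digitizing plus venation variability).

Archetype defaults encode the documented contrasts: ancestral males are
loud (−12 dBFS), tonal (noise mix 0.05), low-frequency (4.8 kHz); purring
males are much quieter (−40 dBFS), strongly broadband (0.70), lack
mirrors, have reduced harps, and their **calling-song** carrier depends on
scraper state — 7.6 kHz with a scraper, 13.6 kHz without, the published
medians — with within-class SD 2.5 kHz, the spread implied by the
published contrast (t = −4.66 on those medians with df = 13.6); scraper
prevalence is the published 16/27. Courtship songs use the archetype's
generic carrier (the scraper result concerns calling song) at a slightly
higher frequency and lower level. Rattling males are intermediate
(−24 dBFS, mix 0.30, 5.8 kHz) with file gaps and 12/13 scraper
prevalence. Amplitudes in dBFS, harp widths and mirror sizes in mm are
plausible defaults, not field measurements.

Every individual draws from its own RNG stream derived by hashing the
cohort seed with the individual's index, so cohorts are bit-reproducible
and stable under changes of cohort size; generators never disturb the
caller's RNG state.

What the generator does **not** emulate: pulse/syllable temporal structure
beyond a fixed pulse rate, frequency modulation within pulses, resonator
physics linking wing geometry to spectra (the form–song couplings in
synthetic data arise only through the archetype parameters), population
structure, and recording artefacts beyond the stationary noise floor.
Passing tests therefore demonstrate that the pipeline recovers structure
of this kind when present at these magnitudes — not that real field data
contain such structure.

## Problem sizes and reproducibility

The default study-scale computation is a 59-individual cohort (0.5 s
songs at 44.1 kHz, calling + courtship, one wing each), gap statistic
with `k_max = 10` and `B = 50` reference datasets; this runs in a few
seconds on one CPU. Unit and property tests use smaller fixtures (20–40
individuals, `B` = 15–30, 0.25–0.3 s songs) chosen so the full suite
completes in about a minute. Pipeline reports contain no timestamps, so a
rerun with the same configuration and seed is byte-identical — a property
the tests assert file-by-file.

## Known limitations

- Dominant frequency is the argmax bin; no parabolic interpolation or
  harmonic analysis. At window 256 the ~172 Hz bin spacing bounds
  precision.
- GPA assumes landmark correspondence and no sliding semilandmarks.
- The gap statistic inherits the known sensitivity of cluster-number
  selection to the null reference; both reference spaces are exposed and
  recorded in results.
- The decoupling summary is a significance-pattern heuristic, not a formal
  test of slope heterogeneity across morphs.
- Firth contrasts treat trials as independent; repeated measures per
  female are not modelled.
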