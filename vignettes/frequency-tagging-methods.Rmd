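---
title: "Methods: frequency-tagged cortical tracking, the N400 contrast, and the synthetic cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-tagged cortical tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The paradigm and its arithmetic

In a hierarchical frequency-tagging design, synthesized speech is built
from isochronous monosyllabic words (320 ms each by default). Four words
form a sentence (1.28 s), two-word phrases sit inside each sentence, and
twelve sentences form a trial. Because the linguistic units tile the
stream perfectly, each level of structure is "tagged" at a fixed rate:

* sentential: 1/1.28 s = 0.78125 Hz,
* phrasal: 2/1.28 s = 1.5625 Hz,
* syllabic: 4/1.28 s = 3.125 Hz.

A listener who parses the structure shows spectral peaks of neural
activity at all three rates even though only the syllabic rate is
physically present in the acoustics; a listener who does not parse the
higher structure shows peaks only at the lower levels of the hierarchy.

The first sentence of each trial is discarded to avoid the auditory onset
transient, leaving an 11-sentence, 14.08 s analysis epoch with a spectral
resolution of 1/14.08 = 0.071 Hz. The design guarantees that every tagged
rate completes an integer number of cycles inside this epoch (11, 22, and
44 cycles), so each rate sits exactly on a DFT bin and spectral leakage
is structurally zero: no taper is needed or used. `entrainr` carries
durations internally as integer milliseconds so this bin alignment is
exact by construction rather than approximate in floating point;
`bin_index()` still verifies alignment to a configurable tolerance
(default 1e-6 cycles) and refuses misaligned frequencies. Printed
frequencies are rounded half-to-even at two decimals (0.78, 1.56, 3.12),
the convention that matches all three display values simultaneously;
internal computation always uses the exact rationals.

## Tagging analysis

Per subject, retained trials are averaged in the time domain first
("evoked" averaging, which suppresses non-phase-locked activity), and the
average is transformed with the FFT. Power at a non-DC bin `k` is
`(2 |X_k| / N)^2`, so a 1 µV sinusoid that tiles the epoch reads exactly
1 µV² (0 dB re 1 µV²). Powers are converted to dB *before* any
averaging or subtraction: a difference in dB is a power ratio, which
makes the neighbor contrast a relative, floor-independent quantity.

The local noise floor is removed by neighbor-bin normalization: from each
bin's dB power, subtract the mean dB power of the two bins on each side
(four neighbors total). The per-subject statistic at each tagged rate is
the pair (peak-bin power, neighbor-mean power), each first averaged over
the retained scalp electrodes in dB. The group test is a one-tailed
paired t test across subjects with the directional alternative
"peak > neighbors"; reversing the roles of the two columns only flips the
sign of t, so the convention is stated here once and used everywhere.
The DC bin is excluded from every statistic, and bins lacking a full
neighbor set are undefined rather than padded.

Two caveats on the peak statistic are worth recording. First, because a
1/f background falls with frequency, the neighbor mean at a low bin is
very slightly biased above the peak bin (about -0.1 dB at the sentential
bin with the default resolution); the null simulations in the test suite
confirm that the type-I error of the one-tailed test stays at its nominal
level despite this. Second, monotonicity — a larger injected amplitude
giving a larger peak-minus-neighbor estimate with the noise realization
held fixed — holds deterministically once the tagged power exceeds the
per-bin noise floor; below the floor, phase interference between signal
and noise at the peak bin can transiently offset a small amplitude
increment, which is why the monotonicity test operates in the
signal-dominant regime.

## Preprocessing

Both experiments share the preprocessing layer:

* **Filtering.** Hamming-windowed-sinc FIR band-pass (0.1–25 Hz for the
  tagging analysis, 0.1–30 Hz for the ERP analysis), with the order rule
  `ceil(3.3 / (tw / fs))` and transition width
  `tw = min(lo, 0.1 * hi)`. The filter is applied forward–backward for
  zero net phase; since a linear-phase FIR cascaded with its reverse
  equals one convolution with the squared-magnitude response, the
  implementation performs a single FFT-domain pass per channel with edge
  reflection absorbing the transients. Passband gain is within 1 % of
  unity and stopband attenuation exceeds 40 dB one transition width
  beyond the edges.
* **Referencing.** Common average for the tagging analysis; linked
  mastoids (labels TP9/TP10 in the bundled montages) for the ERP
  analysis. Channel exclusion — the temporally noisy set T7/T8/TP7/TP8
  plus configurable frontal channels standing in for ocular-artifact
  removal — happens *before* the common average is formed.
* **Interpolation.** Bad channels are rebuilt as the
  inverse-distance-weighted mean of their Delaunay-triangulation
  neighbors among good channels, on the montage's schematic 2-D layout.
  The triangulation is the brute-force empty-circumcircle construction,
  entirely adequate for 64 electrodes. All bad channels are interpolated
  from the original data, so the result does not depend on processing
  order; a bad channel with no good neighbor is an error, not a guess.
* **Epoching.** Sample windows are half-open `[round(e + tmin*fs),
  round(e + tmax*fs))` with 0-based event indices; event times are
  sample indices, never seconds, to avoid float drift. ERP epochs run
  -100 to 700 ms (800 ms, 400 samples at 500 Hz); tagging epochs drop
  the first sentence simply by starting at `tmin = 1.28` s.
* **Rejection and baseline.** ERP epochs are baseline-corrected to the
  pre-stimulus mean (-100 to 0 ms) and then rejected if the absolute
  amplitude on any retained channel exceeds 75 µV. The threshold is
  deliberately applied after baseline correction (the alternative order
  is defensible; this one was fixed here and is used consistently), and
  the scan covers all scalp channels, not only the ROI.

## ERP analysis

Per subject, retained epochs are averaged within each congruency
condition. The window statistic averages each condition over a 14-channel
central/centro-posterior ROI (C5, C3, C1, Cz, C2, C4, C6, CP5, CP3, CP1,
CPz, CP2, CP4, CP6) and a half-open time window — 300–500 ms and
500–700 ms by default — and tests the incongruent-minus-congruent
difference across subjects with a two-tailed paired t test plus the 95 %
confidence interval of the mean difference. Inference is subject-level
throughout.

The point-wise map runs a paired t test at every (electrode, sample) and
controls the false discovery rate with Benjamini–Hochberg over the *joint*
electrode-by-time family, the more conservative reading when the family
is not otherwise specified. Because FDR control tolerates isolated false
positives by design — and produces them liberally once a large true
effect region relaxes the step-up threshold — effect-onset latency is
summarized as the earliest *sustained* significant run (default 20 ms)
on the ROI channels, not the earliest isolated significant sample.

## Shared statistics

Paired and pooled-variance independent t tests wrap `stats::t.test`;
between-group behavioral comparisons use the independent pooled test with
`df = n1 + n2 - 2`, which is the correct analysis for two distinct
groups. Spearman correlations are Pearson correlations of mean ranks with
a two-sided p from the t approximation on `n - 2` df (an exact
permutation p is available behind a flag for n ≤ 10). Cohort measures
are min–max scaled before correlation to mirror the common reporting
convention; scaling is strictly monotone, so it provably leaves every
rank correlation unchanged — the test suite asserts the identity exactly.
Benjamini–Hochberg is delegated to `stats::p.adjust`.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline can be validated
against known ground truth without any data download. Its choices:

* **Tracking signal.** Phase-locked sinusoids at exactly the tagged
  rates, with per-subject amplitudes (µV), uniform random phases, and a
  focal fronto-central gain topography in [0, 1]. The analysis only
  interrogates the tagged bins, so sinusoids give analytically known
  ground truth; per-syllable evoked transients are deliberately not
  modeled. A consequence of an all-positive gain map is that the common
  average removes the coherent mean of the topography — the focal map
  (Gaussian, SD 0.3 in layout units) keeps that loss modest, as a
  dipolar field would in real data.
* **N400.** Each critical word adds a Gaussian-windowed deflection
  (SD 80 ms) centered at the subject's latency, scaled by a
  centro-parietal ERP gain map. The congruent condition carries a
  baseline deflection (-0.5 µV ROI-window mean); the incongruent
  amplitude is offset so that the ROI-mean incongruent-minus-congruent
  amplitude over 300–700 ms equals the subject's `n400_effect` exactly in
  the noise-free limit — the generator divides out the discrete
  template/window overlap and the ROI gain mean, so recovery error at
  500 Hz is a small fraction of a percent.
* **Background.** 1/f ("pink") Gaussian noise per channel, RMS set by
  `noise_scale` (default 10 µV), generated by spectral shaping; its
  periodogram slope on log-log axes is -1 by construction.
* **Artifacts.** With probability `artifact_rate` per event-aligned
  segment, a ±(100–300) µV boxcar lands on a random subset of
  inner-layout channels over a random 200 ms sub-interval. The default
  rate of 0.123 makes the rejection stage's expected exclusion fraction
  about 12.3 % of trials. Ground-truth positions ride along in the
  recording metadata, so rejection can be checked exactly. Mastoid and
  other outer-ring channels are spared so the reference stays clean;
  ocular sources are not modeled separately — channel exclusion plus
  amplitude rejection stand in for them.
* **Cohorts and coupling.** Group parameter sets are drawn from
  log-normal marginals for amplitude-like quantities and normal marginals
  for latencies and behavioral scores. The sentential amplitude and the
  N400 effect *magnitude* are coupled through a Gaussian copula whose
  latent correlation is `2 sin(pi * rho_S / 6)`, giving the requested
  Spearman coupling exactly in population; the canonical negative sign of
  the effect then makes the empirical tracking-vs-effect correlation come
  out negative. Subject seeds derive deterministically from the cohort
  master seed, so a cohort is a pure function of its spec.

**Group defaults.** The two built-in groups encode the qualitative
contrast of interest: the native-like group (NL) has all three amplitudes
positive (medians 1.0/1.2/1.5 µV), an N400 effect of median -1.2 µV at
400 ms; the second-language-like group (SL) has essentially no sentential
amplitude (median 0.02 µV, retained as a non-degenerate marginal for the
copula), phrasal/syllabic amplitudes preserved, and a smaller
(median -0.9 µV), later (450 ms) N400. Behavioral scores (comprehension
rating 0–4, question accuracy, listening score) are drawn from clipped
normal distributions whose means separate the groups.

**SNR calibration.** The default amplitudes, noise RMS, and topography
widths were fixed together, once, so that a 22-subject cohort at the
bundled configuration reproduces the qualitative pattern — significant
peaks at all three rates for NL, no sentential peak but intact
phrasal/syllabic peaks for SL, canonical N400 effects in both groups with
the NL effect starting earlier — across the bundled seeds. The procedure
was: fix noise at a realistic 10 µV RMS, then raise the amplitude medians
from zero until the per-subject dB elevation at the weakest (sentential)
bin comfortably exceeded its across-subject standard error at n = 22.
These values are frozen in the defaults and are design constants of the
simulator, not estimates of any real effect size, for which no µV ground
truth exists.

**What the generator does not emulate.** No leadfield/head-model
projection (gains are schematic scalar maps), no ocular or muscle source
with its own topography, no trial-to-trial latency jitter of the N400, no
correlation between behavioral scores and neural parameters (only the
amplitude–N400 coupling is modeled), and no acoustic stimulus. Passing
tests therefore demonstrate that the *analysis* is correct and well
calibrated on signals with these statistics; they cannot certify
performance on real recordings, whose artifacts and topographies are
richer. Note also that because the SL group's sentential amplitude is
essentially zero by design, its measured sentential peak is noise, and
the pipeline's SL tracking-vs-N400 correlation is correspondingly near
zero; a cohort intended to *exhibit* that correlation should be drawn
with a positive sentential amplitude median and a nonzero
`coupling_rho`, which is exactly what the coupling-recovery experiments
do.

## Problem sizes used by the test and acceptance suites

Statistical properties (test level, CI coverage, FDR control, coupling
recovery) do not depend on the full recording dimensions, so the
simulation experiments run at reduced, fixed sizes chosen as the
package's own validation conditions: the type-I experiment uses
two-channel, three-trial recordings at 100 Hz (1000 cohorts of n = 22);
detection uses an eight-channel fronto-central montage, 15 trials at
125 Hz (20 cohorts per group, master seeds 1–40); the ERP coverage and
FDR experiments use a seven-channel ROI montage at 200 Hz with 4–6
sentences per condition (500 and 200 cohorts of n = 22). The bundled
pipeline configuration runs both 22-subject groups at the full 500 Hz
with a 24-channel working montage, 10 tagging trials, and 16 sentences
per condition, completing in minutes on one CPU; the full 64-channel
montage (`preset = "full64"`), 30 trials, and 53 sentences per condition
are available by editing the config.

## Known limitations

* The Delaunay construction is O(n^4) in channels; fine at 64, not meant
  for high-density nets.
* `fir_bandpass` at 0.1 Hz and 500 Hz uses a ~16 500-tap filter; the FFT
  implementation makes this cheap, but recordings much shorter than the
  filter will be dominated by edge reflection.
* The exact-permutation Spearman p enumerates all n! permutations and is
  only offered for n ≤ 10.
* Generators call `set.seed()` internally (purity of output given the
  seed is the contract), so they perturb R's global RNG stream; wrap
  calls in `withr::with_seed()` if the surrounding stream matters.
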