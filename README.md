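# entrainr

Analysis pipeline for **hierarchical frequency-tagging EEG experiments**
— designs in which synthesized speech is built from isochronous
monosyllabic words so that syllables, two-word phrases, and four-word
sentences occur at fixed, harmonically related rates — together with an
**N400 semantic-congruency ERP analysis** and the cohort-level
correlation that links cortical tracking of linguistic structure to
language comprehension. It is aimed at cognitive-neuroscience and
neural-signal-analysis work where listeners (for example native versus
second-language groups) differ in how far up the linguistic hierarchy
their cortical activity tracks the stimulus.

The package also ships a **deterministic synthetic-EEG cohort
generator** with known ground truth — phase-locked sinusoids at the
tagged rates, Gaussian-template N400 deflections, 1/f background noise,
boxcar artifacts, and Gaussian-copula coupling between tracking
amplitude and N400 effect size — so every stage of the pipeline is
verifiable without any data download.

## The core computations

With 320 ms syllables, four-word sentences (duration `T = 1.28` s) and
the first of twelve sentences per trial discarded, the analysis epoch is
`11 T = 14.08` s with spectral resolution `1/14.08 = 0.071` Hz, and the
tagged rates

    sentential 1/T = 0.78125 Hz,  phrasal 2/T = 1.5625 Hz,  syllabic 4/T = 3.125 Hz

fall exactly on DFT bins 11, 22, 44 of the epoch (no taper, zero
leakage). Per subject the pipeline computes **evoked power** — the
one-sided spectrum of the trial-averaged signal, `P_k = (2|X_k|/N)^2` in
dB re 1 µV² — and the **neighbor-bin contrast** `P_peak − mean(P_k)`
over the four flanking bins (two per side), electrode-averaged in dB.
Each tagged rate is then tested across subjects with a one-tailed paired
t test (`peak > neighbors`).

The ERP side epochs −100…700 ms around critical-word onsets, rejects
epochs exceeding ±75 µV after mastoid referencing and baseline
correction, averages per congruency condition, and tests the
incongruent-minus-congruent ROI mean (14 central/centro-posterior
channels) in the 300–500 and 500–700 ms windows with paired t tests,
plus a point-wise electrode × time map under Benjamini–Hochberg FDR.
Cohort measures are min–max scaled and related by Spearman correlation.

## Worked example

```r
library(entrainr)

## paradigm arithmetic
spec <- paradigm_spec()              # 320 ms syllables, 12-sentence trials
tag_frequencies(spec)
epoch_duration(spec); round(frequency_resolution(spec), 3)

## a small synthetic native-listener cohort, analysed end to end
m <- make_montage("desk24")
desk <- paradigm_spec(n_trials = 6L, fs_hz = 250)
cohort <- draw_cohort(cohort_spec("NL", n_subjects = 8, master_seed = 42))

pairs <- lapply(cohort, function(sp) {
  rec <- simulate_entrainment(sp, desk, m)
  process_entrainment_subject(rec, desk, m)$pairs
})
peak <- sapply(pairs, function(p) p$peak_db[p$rate == "sentential"])
nbrs <- sapply(pairs, function(p) p$neighbor_db[p$rate == "sentential"])
group_peak_test(peak, nbrs, rate = "sentential")

## N400 window contrast for the first three subjects
erps <- lapply(cohort[1:3], function(sp) {
  rec <- inject_artifacts(simulate_n400(sp, 16, m), sp)
  process_n400_subject(rec)$erps
})
roi_window_effect(erps, win_ms = c(300, 500))
```

This prints:

```
sentential 0.78 Hz, phrasal 1.56 Hz, syllabic 3.12 Hz
[1] 14.08
[1] 0.071
peak test [sentential]: t(7) = 2.586, one-tailed p = 0.01807, mean diff = 1.32 dB *
ROI effect 300-500 ms: -3.199 uV, t(2) = -2.97, p = 0.09686, CI95 = [-7.83, 1.43]
```

Reading the numbers: the tagged rates and epoch constants are the design
arithmetic; the peak test says that across the eight simulated native
listeners, power at the sentential bin exceeded its neighbor-bin floor
by 1.32 dB on average (significant, one-tailed); the ROI contrast shows
a negative (canonical) congruency effect of −3.2 µV in the 300–500 ms
window, not significant with only three subjects, with its 95 % CI.

## The full pipeline

`run_pipeline()` (or the CLI, `Rscript inst/cli/entrainr.R run-all
--config inst/extdata/default_config.json --out out/`) simulates both
22-subject groups, runs every analysis stage, and writes a cohort table
(TSV) plus JSON stage reports (tagging peak tests per rate and group,
N400 window effects and FDR-map onset latencies, artifact-rejection
fractions, behavioral group contrasts, and the second-language
correlations). The run is byte-reproducible given the master seed. The
CLI also exposes `simulate`, `preprocess`, `tag`, `erp`, and `correlate`
subcommands over the same bit-exact recording container (JSON header +
little-endian float32 + events TSV).

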