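# nrr: respiratory rate from neonatal NIRS intensity signals

Critically ill neonates are monitored for apnea and tachypnea, and their
cerebral perfusion is increasingly watched with near-infrared spectroscopy
(NIRS). Raw NIRS hemoglobin signals carry respiration, heartbeat, Mayer
waves, and drift as "physiological noise" — which means a single optical
sensor can, in principle, deliver cerebral oximetry, heart rate (HR), and
respiratory rate (RR) at once, perfectly time-synced. `nrr` implements an
RR extractor designed for that setting: 100 Hz two-channel neonatal NIRS
recordings, low signal quality, and frequent motion artifacts.

The package is aimed at biomedical-signal researchers who want to run,
stress-test, or extend the algorithm without access to clinical
recordings: a synthetic neonatal-NIRS generator with known HR/RR ground
truth makes every stage testable.

## The algorithm

Given a two-channel recording (optical densities or O2Hb/HHb concentration
changes), the pipeline works on tHb = O2Hb + HHb:

**Stage A** (once per measurement)

1. *Preprocessing.* OD is converted to concentration changes with the
   modified Beer–Lambert law; each channel is scored by a signal-quality
   index (SQI, levels 1–4, proxied by the cardiac-band power ratio); the
   channel with the greater mean SQI is selected, and the measurement is
   excluded when more than 75% of its SQI windows are below level 2.
2. *HR frequency bandwidth.* tHb is high-passed by subtracting a 1-s
   moving average; its multitaper PSD (Slepian tapers, NW = 2.5, K = 5)
   is resampled to 100 components in the predefined cardiac band
   1.25–3.5 Hz (75–210 BPM); the mean frequency f̄ of the 50 strongest
   components defines BW_HR = [f̄ − 0.5, f̄ + 0.5] Hz.
3. *IQR series.* The interquartile range of tHb in sliding 1-s windows,
   cubic-interpolated back to 100 Hz and normalized by |median(tHb)|.
4. *Segmentation.* 30-s windows shifted by 7.5 s (75% overlap).

**Stage B** (per segment)

5. *Motion gate.* The binary mask is 1 where the normalized IQR < 1%;
   segments less than 50% clean are dismissed.
6. *HR.* The segment is linearly detrended, multiplied by the mask, and
   HR = 60 × argmax of the multitaper PSD inside BW_HR.
7. *RR.* The masked segment is band-passed with a zero-phase Kaiser FIR
   to [0.1·HR, 2] Hz, and RR = 60 × argmax of the PSD inside the adaptive
   band BW_RR = [0.15·HR, min(0.85·HR, 2 Hz)].

Two comparator extractors are included — fixed band-pass filtering (BPF,
0.15–2 Hz, no artifact gating) and a reconstructed baseline-wander (BW)
method — plus an agreement suite (bias ME, RMSE, Bland–Altman limits of
agreement 1.96·sd, Pearson r, the 30% error boundary, paired t-tests) and
a sequential sensitivity sweep over window length and the BW_RR constants.

## Worked example

```r
library(nrr)
cfg <- sim_config(duration_s = 300, seed = 42, hr_bpm = 150,
                  rr_bpm = rbind(c(0, 40), c(150, 52), c(300, 44)),
                  artifact_rate = 2)
sim <- simulate_measurement(cfg)
res <- run_nrr(sim$recording)
head(res, 4)
#>   method start_s included clean_frac   hr_bpm   rr_bpm band_rr_lo band_rr_hi
#> 1    nrr     0.0     TRUE  0.8393333 149.9634 41.01562  0.3749084          2
#> 2    nrr     7.5     TRUE  0.8393333 151.9775 43.57910  0.3799438          2
#> 3    nrr    15.0     TRUE  0.8393333 147.9492 40.46631  0.3698730          2
#> 4    nrr    22.5     TRUE  0.9036667 153.8086 45.04395  0.3845215          2

agreement(align_reference(sim$reference, res))
#> <agreement over 37 pairs>
#>   ME     -0.70 BPM
#>   RMSE    1.90 BPM
#>   LoA     3.51 BPM
#>   r      0.833 (p = 1.58e-10)
#>   included 100.0%
```

The five-minute fixture drifts between 40 and 52 breaths/min with two
motion bursts per minute; every 7.5 s the extractor reports the segment's
HR and RR (or dismisses the segment when it is mostly artifact). The
agreement report compares each RR against the mean of the fifteen 0.5 Hz
reference samples in the same 30-s window: bias −0.7 BPM, RMSE 1.9 BPM,
and a significant correlation despite the artifacts, with no segment
lost. A command-line wrapper (`exec/nrr`) exposes the same pipeline as
`simulate`, `extract`, `evaluate`, and `compare` subcommands.

## Vignette

`vignettes/nrr-methods.Rmd` documents the model and its assumptions, the
tunable parameters, what the synthetic generator does and does not
emulate, the numerical design choices, and known limitations (notably
the spectral-window resolution limit on argmax-based rate estimates).
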