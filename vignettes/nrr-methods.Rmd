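---
title: "Extracting respiratory rate from neonatal NIRS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting respiratory rate from neonatal NIRS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physiological model

Respiration modulates cerebral blood volume and systemic blood flow, so a
raw NIRS hemoglobin signal recorded on a neonate's forehead contains a
respiratory oscillation well below the cardiac pulsation, alongside Mayer
waves (~0.1 Hz), slow hemodynamic drift, broadband instrument noise, and
— in an intensive-care setting — frequent large motion artifacts. `nrr`
works on total hemoglobin, tHb = O2Hb + HHb, because respiration is
present in both chromophores and summing improves its representation.

Two assumptions underpin the extraction:

* the neonatal heart rate stays inside 75–210 BPM (1.25–3.5 Hz), so a
  cardiac line can always be sought in that predefined band; and
* the respiratory rate lies well below the heart rate — the adaptive
  search band [0.15·HR, 0.85·HR] encodes this and keeps the cardiac line
  and its subharmonic neighbourhood out of the RR search.

The per-segment HR therefore serves primarily to aim the RR band: an
error in HR shifts BW_RR proportionally, which is tolerable as long as
the true RR stays inside the shifted band.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `seg_len_s` | 30 | s | segment length; the sensitivity sweep confirms 30 s against 20–60 s |
| `overlap_frac` | 0.75 | – | 7.5-s hop; RR is reported every 7.5 s |
| `iqr_win_s` | 1 | s | dispersion window for artifact detection |
| `iqr_threshold` | 0.01 | – | mask threshold on the median-normalized IQR |
| `clean_min_frac` | 0.5 | – | minimum clean fraction for inclusion |
| `hr_band_lo/hi` | 1.25 / 3.5 | Hz | predefined cardiac band (75–210 BPM) |
| `hr_halfwidth` | 0.5 | Hz | half-width of the adaptive HR band |
| `topk_components` | 50 | – | components averaged for the HR band centre |
| `grid_components_in_band` | 100 | – | in-band resampling grid (see below) |
| `bpf_lo_factor`, `bpf_hi` | 0.1, 2.0 | –, Hz | Kaiser band-pass ahead of RR estimation |
| `a_low`, `a_high` | 0.15, 0.85 | – | adaptive RR band as fractions of HR |
| `nw`, `k` | 2.5, 5 | – | Slepian time-bandwidth product and taper count |
| `nfft_factor` | 8 | – | zero-padding of segment spectra |
| `kaiser_atten_db`, `kaiser_trans_hz` | 50, 0.1 | dB, Hz | FIR design targets |

All of these live in `nrr_params()` and can be swept with
`sensitivity_grid()`, which reproduces the sequential optimisation
procedure (window length first at the widest band, then `a_low`, then
`a_high`, preferring the band-enlarging value whenever cells are
statistically tied at the 5% level).

## What the synthetic generator emulates

`simulate_measurement()` builds tHb as a sum of interpretable parts:
a cardiac sinusoid whose phase integrates the instantaneous HR
trajectory, a respiratory sinusoid likewise driven by the RR trajectory,
a narrowband Mayer component (slow random phase walk around 0.08 Hz),
sub-0.02 Hz drift, white noise, and Poisson-arriving motion bursts of
boxcar-windowed random steps whose amplitude dwarfs the cardiac
pulsation. Components are split equally between O2Hb and HHb; the second
channel carries the same physiology scaled down so channel selection has
a meaningful job; a constant operating point (default 60 µM, a plausible
neonatal total-hemoglobin scale) gives the median-normalized IQR
statistic a physiological denominator.

Amplitude defaults (cardiac 0.25 µM, respiratory 0.15 µM, Mayer 0.08 µM,
drift 0.5 µM, noise 0.05 µM) were chosen once for testability — a clean
segment's normalized IQR sits just under the 1% threshold, and a burst
clears it by an order of magnitude — not as a fitted model of any
patient population, since amplitude ratios of these components in
neonatal tHb are not well characterised.

The generator deliberately does **not** emulate: non-sinusoidal
respiratory waveforms, apnea/desaturation pathophysiology beyond what a
trajectory dip can express, optode–tissue optics, correlated noise, or
channel cross-talk. Passing tests on these fixtures therefore
demonstrate algorithmic correctness (band placement, gating, agreement
arithmetic), not clinical performance.

## Numerical choices

**Slepian tapers.** No taper routine is assumed from the host system;
`src/dpss.cpp` computes discrete prolate spheroidal sequences from the
classic symmetric tridiagonal operator by Sturm-count bisection plus
inverse iteration — O(n) per taper, so whole-measurement spectra (n of
order 10^5) remain cheap. Taper sets and FIR designs are cached per
session.

**Spectra.** Eigenspectra are averaged unweighted (all five eigenvalues
at NW = 2.5 are close to one); spectra are one-sided densities whose
integral matches the tapered-signal variance. Segment spectra are
zero-padded to the next power of two at or above eight times the segment
length (≈0.003 Hz grid at 100 Hz/30 s).

**The in-band resampling grid.** The top-50 averaging that centres the
HR band operates on exactly 100 uniformly spaced in-band frequencies,
whatever the record length. Without this, the number of native FFT bins
in 1.25–3.5 Hz — and hence the meaning of "the 50 strongest components"
— would depend on the measurement duration.

**Zero-phase Kaiser filtering.** The band-pass is a linear-phase FIR
designed by the Kaiser-window formulas (beta from the attenuation
target, order from the transition width), applied forward-backward. The
two passes are collapsed into a single frequency-domain multiplication
by |H(ω)|² — a real, hence zero-phase, composite response — on a
reflection-padded extension of the segment (pad three times the filter
order), with enough zero padding that the circular wrap-around stays in
the discarded pad. At 100 Hz the 0.1 Hz transition target would require
~2900 taps, more than a 30-s segment can support; the order is capped at
a third of the segment length (998 taps), keeping the 50 dB window shape
while letting the transition widen to ~0.3 Hz. After the
forward-backward application the stop-band attenuation doubles in dB,
so DC and the cardiac line are still suppressed far below the
respiratory line.

**IQR series.** The 1-s windows hop by half a window; window-centre
values are cubic-spline interpolated to the 100 Hz grid with edges held
at the nearest computed value, and negative spline overshoot is clipped
at zero. The normalizer |median(tHb)| is floored at a configurable
epsilon (10⁻⁶) with a warning, which handles zero-mean concentration
inputs without crashing while making the degeneracy visible.

**Boundary semantics.** All gates are taken literally from their
defining phrases and are strict on the dismissing side: a sample is
clean when its IQR is strictly below the threshold; a segment is kept at
exactly 50% clean; a measurement is kept at exactly 75% low-quality
windows. Ties in `dominant_frequency` resolve to the lowest frequency;
channel-selection ties resolve to the lowest channel index.

**Degenerate inputs.** Constant segments, empty bands on the grid, and
zero in-band power all signal failure rather than fabricate a rate; a
segment whose RR band collapses is marked not included. A measurement
failing the quality rule raises a typed condition
(`nrr_excluded_measurement`), which the CLI maps to exit status 3.

## Design decisions taken where the design was open

* **SQI proxy.** The published quality scorer is external to this
  package; quality here is the ratio of cardiac-band (1.25–3.5 Hz) power
  to total power above 0.5 Hz, bucketed into levels 1–4 by configurable
  thresholds — following the observation that optical coupling shows up
  as heartbeat strength. "Samples of the SQI" is read as SQI windows.
  The averaging for channel selection is over levels.
* **Mask after detrend.** The segment is detrended first and then
  multiplied by the mask, leaving artifact gaps at zero rather than
  interpolating through them.
* **BW_RR upper clip.** When 0.85·HR exceeds 2 Hz the band is clipped at
  2 Hz, since the preceding filter suppresses everything above it
  anyway.
* **Baseline-wander comparator.** Reconstructed as: centred moving
  average over 0.6 s (removes cardiac pulsation, passes breathing),
  then the dominant in-band spectral frequency of that baseline. Its
  results carry a `reconstructed` flag; it is a plausible stand-in, not
  a fidelity claim, and it is excluded from quantitative ordering
  claims in the tests.
* **Method comparison pairing.** The t-test between methods pairs
  per-segment absolute errors on the shared segment grid (chosen for
  power over per-measurement pairing; both views are available from the
  returned tables).

## Known limitations

* **Spectral-window resolution.** The multitaper spectral window is
  flat-topped over roughly ±NW/T (±0.083 Hz for 30-s segments) with
  sub-percent ripple, and the phase-dependent interference from a line's
  negative-frequency image is enough to move the in-band argmax between
  ripple crests. Rate estimates therefore carry an intrinsic
  quantization-like error of up to ~4 BPM regardless of FFT zero-padding
  — zero-padding refines the grid, not the window. This is a property
  of argmax-on-multitaper rate readers generally; it is visible in the
  package's tests as a bounded wobble on noiseless fixtures and sets
  the floor on achievable RMSE (~2 BPM for constant-rate fixtures).
* **Synthetic validation only.** Everything quantitative in the test
  suite is established on the generator above; clinical recordings
  differ in artifact morphology, spectral content, and reference-monitor
  behaviour.
* **Offline design.** Stage A uses the whole measurement (channel
  selection, HR band); a streaming variant would need windowed
  re-estimation of both.

## Problem sizes used by the test suite

The suite establishes parameter recovery on a 10-minute noiseless
fixture, artifact robustness on twenty 3-minute fixtures per artifact
coverage level (5/15/30% of the record), and the NRR-vs-BPF ordering on
twenty 30-minute fixtures with time-varying rates — sizes picked so the
full suite exercises every stage at measurement scale while staying
comfortably interactive.
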