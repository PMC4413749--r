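---
title: "Methods: calibrated acoustic-habitat metrics in pamscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated acoustic-habitat metrics in pamscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamscape)
```

pamscape turns raw audio from passive acoustic monitoring (PAM) recorders —
microphones in air, hydrophones underwater — into absolute sound-pressure
measurements, and computes the standard statistical and spectral metrics
used to characterise acoustic habitats. This vignette explains the models
and conventions behind each stage, the parameters that matter, and the
limits of what the synthetic test bed can demonstrate.

## The calibration model

A PAM system is a chain: transducer (sensitivity $M$, dB re 1 V/µPa),
pre-amplifier (gain $G$, dB), and analogue-to-digital converter whose
zero-to-peak input voltage $V_{ADC}$ maps to digital full scale. Recovering
pressure from the dimensionless samples $x[n] \in [-1, 1]$ means inverting
that chain. We collapse it to a single combined sensitivity in dB re
full-scale per µPa,

$$S = M + G - 20\log_{10} V_{ADC},$$

so that $p[n] = x[n]\,10^{-S/20}$ µPa. An end-to-end sensitivity measured by
injecting a known reference signal (e.g. a pistonphone tone) can replace
the three components; `cal_spec()` enforces that exactly one
parameterization is supplied. Typical hydrophone chains give strongly
negative $S$ (e.g. $M = -165$, $G = 20$, $V_{ADC} = 1$ V gives
$S = -145$ dB, i.e. full scale is about 178 dB re 1 µPa zero-to-peak).

Conventions worth making explicit:

* **Normalization divisor.** Integer codes are divided by $2^{bits-1}$ (not
  $2^{bits-1}-1$), so the most negative 16-bit code $-32768$ maps to exactly
  $-1.0$ and no code exceeds full scale. This is symmetric and standard;
  the $\tfrac12$-LSB asymmetry at the positive rail is far below any
  acoustic tolerance.
* **Pressure unit.** Pressure is µPa in both domains. Only the reference
  pressure applied at dB conversion differs: $p_{ref} = 20$ µPa in air,
  1 µPa underwater. One code path, one declared `domain`.
* **DC removal.** The segment mean is subtracted before scaling. ADC offset
  is an artefact of the acquisition chain, not sound, and would otherwise
  leak into the lowest PSD bins.
* **Frequency-dependent response.** When a response curve is supplied it is
  interpolated linearly in dB against $\log_{10} f$ — the geometry in which
  datasheet response curves are tabulated — and subtracted bin by bin.
  Analysis frequencies outside the curve clamp to its end values with a
  warning; silently extrapolating a resonance would be worse.
* **Clipping.** A sample is counted as clipped when $|x| \ge 0.99$ of full
  scale. Real limiters and converters rarely park clipped samples exactly
  at the rail, so a threshold just below it catches rounded clips; the
  `clipped_fraction` travels with every object downstream.

## Spectral estimation

All spectra are single-sided Welch estimates. For a segment of length $N$
with taper $w$,

$$P[k] = \frac{|\mathrm{FFT}(w x)[k]|^2}{f_s \sum w^2},$$

doubled at all bins except DC and Nyquist, in units of µPa²/Hz, reported as
dB re $p_{ref}^2$/Hz. Window compensation by $\sum w^2$ makes the full-band
integral equal the mean-square pressure — exactly so for the rectangular
window (Parseval), and to within the window's spectral-leakage error
otherwise — so broadband SPL computed from the PSD agrees with the
time-domain RMS level. Periodograms are averaged arithmetically (in power)
within consecutive intervals of `average_seconds`; `spectrogram()` is the
same estimator with no averaging.

Defaults: Hann window, 50% overlap, density scaling. A periodic (DFT-even)
Hann has coherent gain exactly 0.5 and equivalent noise bandwidth exactly
1.5 bins at any $N$, which the tests assert. Very high overlap (99%) is
supported for impulse inspection but is not the default: it costs a
~50-fold increase in FFTs for smoother time interpolation only.

One-third-octave bands use the base-ten ladder: exact centres
$f_c(n) = 10^{n/10}$ Hz with edges $f_c \cdot 10^{\pm 1/20}$, and
preferred-number nominal labels (band 18 → 63 Hz, band 21 → 125 Hz). A
base-two ladder produces indistinguishable nominal labels in this range;
base ten keeps the arithmetic exact in decimal decades. Band levels
integrate PSD power over the bins whose centre falls inside the band — no
bin splitting. The assignment error is bounded by one bin width at each
edge, which is why the band-sum versus broadband consistency check uses a
0.5 dB tolerance; a filter-bank implementation to ANSI tolerances is a
non-goal. Bands whose upper edge exceeds Nyquist, or which contain no bin,
are dropped.

Sound exposure level is time-domain:
$\mathrm{SEL} = 10\log_{10}\!\big(\sum p^2 \Delta t / (p_{ref}^2 \cdot 1\,\mathrm{s})\big)$,
so for stationary sound $\mathrm{SEL} = \mathrm{SPL} + 10\log_{10} T$.

## Level statistics

Statistics operate on dB-domain level series except the RMS average,
which is the mean of squared pressure before conversion:
$L_{RMS} = 10\log_{10}\overline{10^{L/10}}$. By Jensen's inequality this is
never below the arithmetic dB mean, and with rare loud events it can exceed
the 95th percentile — the reason medians and modes are reported alongside
it.

* **Percentiles / exceedance levels.** Empirical quantiles with linear
  interpolation of order statistics (`quantile()` type 7), stated
  explicitly because percentile conventions differ across software. The
  exceedance accessor maps $L_x$ to the $(100-x)$th percentile.
* **Mode.** Centre of the densest histogram bin (default width 1 dB, a
  compromise between resolving modal structure and empty-bin noise at
  typical 40–60 dB dynamic ranges), ties broken toward the lower level. A
  multimodality flag is set when a second local density peak lies within
  6 dB (power ratio) of the maximum. The 6 dB default is deliberate: a
  70%/30% two-cluster mixture — a clearly bimodal situation in which the
  mode misleads — has a density ratio of $10\log_{10}(7/3) \approx 3.7$ dB
  between its peaks, so a 3 dB gate would miss it. The threshold is a
  parameter.
* **SPD.** The spectral probability density is, per frequency row of a PSD
  grid, the normalized histogram of dB levels over time (units 1/dB; each
  column integrates to exactly 1). It exposes modal structure that averages
  and percentiles flatten, and it reveals instrument limits: where system
  self-noise dominates, the lowest populated level bins converge onto the
  mode, because the floor — not the habitat — sets the quietest recordable
  level.
* **Temporal aggregation.** Grouping by hour of day, day, or month with
  median / RMS / percentile / boxplot statistics per band. Hours are taken
  from timestamps as parsed (recorders stamp local time); no
  daylight-saving adjustment is attempted — that bookkeeping belongs to the
  study, not the toolkit.

Percentiles for composite spectra can be computed either on PSD bins or on
band levels; both routes are exposed (`spectrum_stats()` on a grid,
[dplyr] on a `band_series`) and the caller chooses.

## Impulse metrics

Frequency spectra under-resolve impulses, so impulse amplitudes are
measured on the pressure waveform: zero-to-peak
$20\log_{10}(\max|p|/p_{ref})$, peak-to-peak
$20\log_{10}((\max p - \min p)/p_{ref})$ (at most $20\log_{10}2 \approx
6.02$ dB apart), pulse SEL, and duration as the 90% energy envelope — the
interval between the 5% and 95% crossings of cumulative energy. Crossings
take the first sample at or above threshold, with no sub-sample
interpolation: the bias is under one sample period, and the energy fraction
inside the envelope is $\ge 0.90$ by construction (the overshoot equals at
most the energy of the two crossing samples, which is why envelope accuracy
improves with sampling rate). No background energy is subtracted before
the envelope computation; doing so would introduce an estimator the
measurement convention does not define, and the SNR gate below handles
contaminated pulses instead.

Pulse measurements are gated on signal-to-noise ratio: RMS level of the
pulse window minus RMS level of a disjoint noise window must be at least
10 dB, the conventional validity floor. Pulse windows are supplied by the
caller — detection/picking is out of scope. Pulse SEL is reported both over
the full window and within the envelope (the two differ by at most
$10\log_{10}(1/0.9) \approx 0.46$ dB), since reporting conventions vary.
When a calibration with a frequency-response curve is available, a warning
is raised if the system response varies by more than 3 dB across the
pulse's −10 dB spectral extent: peak metrics assume a flat system over the
pulse's band.

## The synthetic test bed

Every analysis is validated against generated signals carrying
machine-readable ground truth (`attr(x, "truth")`):

* tones whose amplitude $\sqrt2\,p_{ref}10^{SPL/20}$ hits the requested SPL
  exactly;
* white noise whose variance $10^{D/10} p_{ref}^2 f_s/2$ gives the
  requested density in expectation;
* pink noise shaped in the frequency domain to −3 dB/octave, with the
  density anchored at a reference frequency (default 100 Hz) because a
  $1/f$ density has no flat level;
* impulses (decaying sinusoids) rescaled to an exact zero-to-peak level;
* a day/night level step for diel aggregation tests.

`simulate_recorder()` runs the calibration chain forward: sensitivity
scaling, optional flat Gaussian self-noise (specified as an equivalent
pressure density), hard clipping at full scale, quantization to 16/24/32
bits. Generation is deterministic given a seed, and restores the global RNG
state.

What this does and does not show: the generators reproduce the *mechanics*
real data exercise — calibration arithmetic, estimator scalings,
distributional shapes, clipping and floor artefacts — so a passing suite
demonstrates the pipeline is numerically correct. They do not emulate real
soundscapes: no propagation, no wind/rain source physics, no shaped
instrument floors (a real floor rises toward low frequency; flat suffices
to produce the SPD floor-convergence signature), no duty cycles. Field
conclusions still require instrument-specific calibration data.

Problem sizes in the tests and acceptance checks are chosen so the whole
suite runs in about a minute on one core: white-noise calibration checks
use 100 Welch averages at 2 kHz (where the chi-square standard error of the
mean density is well under the 0.2 dB tolerance asserted), 1/3-octave
consistency uses 120 s at a 4096-point FFT, and the estimator-variance law
(variance $\propto 1/K$) is checked at $K \in \{1, 4, 16\}$ over 100–120
realizations, where a factor-4 ratio is resolvable but a tight equality is
not — hence ratio bounds rather than point tolerances.

## Numerical and degenerate-input choices

* Levels of exactly zero power would be $-\infty$; PSD levels floor the
  power at the smallest double before the log, and all-zero windows are
  rejected for RMS/peak/SEL (`abort`, not `NaN`).
* Welch grouping keeps a final averaging interval with fewer segments and
  records `n_segments` per column; segments shorter than one FFT length are
  never formed. Short trailing file segments from `stream_segments()` are
  marked `partial` so batch drivers can exclude them from averages.
* `quantile()` type 7 everywhere; one convention, stated.
* Mixtures require equal length and rate — no implicit resampling.
* The CSV exporters format with `signif(.., 10)` so identical runs are
  byte-identical.

## Command-line use

The package surface is functions-first; `inst/cli/pamscape` is a thin
script over `run_config()`/`run_analysis()` with subcommands `analyze`,
`selftest`, `synth` and `info`. Calibrated metrics refuse to run without a
calibration; `--relative` analyses uncalibrated recordings and watermarks
every output (and the provenance record) as relative dB re full scale,
since mixing calibrated and relative levels is a classic reporting error.
Each run writes a provenance JSON (inputs, configuration, calibration,
package version) beside the artifacts.

## Known limitations

* No fractional-octave filter banks to ANSI class tolerances; TOLs come
  from PSD summation with bin-centre assignment.
* No impulse detection; windows are caller-supplied.
* No compressed audio, no multi-file deployment stitching beyond timestamp
  parsing, no A/C frequency weightings, no particle-motion quantities, no
  biodiversity indices.
* The gridded export is long-form CSV; very large deployments would want a
  chunked binary container, which is left to the caller's storage layer.
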