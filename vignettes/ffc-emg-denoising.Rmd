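---
title: "Comb filtering and envelope extraction for surface EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comb filtering and envelope extraction for surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgcomb)
```

## The problem

Surface EMG (sEMG) records the electrical activity of contracting muscle
through skin electrodes. For human-machine interfaces the quantity of
interest is usually not the raw millivolt-scale signal (energy mainly in
10-250 Hz) but its *linear envelope* (EMG-LE): the low-frequency amplitude
profile obtained by full-wave rectification followed by low-pass filtering,
which tracks contraction level.

Two disturbances routinely wreck the envelope:

* **powerline interference (PLI)** - a 50 or 60 Hz sinusoid plus higher
  harmonics coupled from the mains, often larger than the EMG itself and
  sometimes amplitude-modulated as the coupling changes;
* **motion artifacts** - low-frequency baseline wander (typically below
  20-30 Hz) from electrode-skin relative motion and skin deformation.

Both must be removed *before* rectification, because rectification folds
their energy into the envelope band. The constraint that makes this
interesting is computational: the target platforms are microcontrollers
where every multiplication counts.

## The feed-forward comb filter

The package is built around the two-tap feed-forward comb (FFC)

$$y(k) = x(k) + \alpha\, x(k-N),$$

with the cancellation setting $\alpha = -1$, i.e. a single subtraction per
sample. Its amplitude response is

$$H(f_n) = 2\,\lvert \sin(\pi N f_n) \rvert, \qquad f_n = f/f_s,$$

with nulls at every integer multiple of $f_s/N$ **including DC**, peak gain
exactly 2 midway between nulls, and half-power points a distance
$f_s/(4N)$ from each null. Choosing $N = f_s/f_\mathrm{pli}$ therefore
places nulls on the powerline fundamental and *all* of its harmonics, while
the zero DC gain and the first cutoff at $f_\mathrm{pli}/4$ (12.5 Hz for
the 50 Hz design at 1 kHz) simultaneously remove offset voltages and
baseline wander. One subtraction removes both nuisances at once.

The $\alpha = +1$ variant (`ffc_response()` and `ffc_nulls()` support it)
nulls only odd multiples of $f_s/(2N)$ and is kept for response analysis;
it is not useful for powerline removal because even harmonics pass.

`ffc_delay()` refuses a non-integer $f_s/f_\mathrm{pli}$ rather than
rounding: a rounded delay shifts every null off its harmonic and the
cancellation degrades silently, which is the worst possible failure mode
for an unattended device. The error message names the nearest admissible
sampling frequencies instead.

The comb notches are wide ($f_\mathrm{pli}/2$ at half power around every
harmonic), so the filter visibly distorts the raw EMG waveform. The
package's evaluation protocol quantifies exactly why this does not matter
for envelope extraction - the envelope lives below 5 Hz and is essentially
untouched - and why the same filter is *not* appropriate for diagnostic
EMG, ECG or EEG, whose in-band morphology the notches would damage.

## Envelope extraction

`linear_envelope()` cascades rectification and a causal moving average.
The window/cutoff mathematics is in `ma_cutoff_hz()`: a $W$-sample average
has magnitude $\lvert\sin(\pi W f/f_s)/(W \sin(\pi f/f_s))\rvert$, and the
-3 dB point is found by bracketed root search between DC and the first
response null $f_s/W$ (the magnitude is 1 at DC and 0 there, so the
bracket always holds; the root is polished far below $10^{-6}$ Hz). Two
operating points recur:

* window 88 at 1 kHz → 5.03 Hz, the offline analysis setting ("5 Hz");
* window 128 at 1 kHz → 3.46 Hz. This is the streaming setting, usually
  quoted as "about 4 Hz"; the package reports the computed value and does
  not round it to the quoted approximation.

Block mode averages non-overlapping windows and decimates to
$f_s/\mathrm{window}$ (7.81 envelope samples/s for 128 at 1 kHz). The
window must be a power of two so integer hardware can replace the division
by a right shift - that constraint is enforced in `envelope_config()`
rather than discovered on the device.

All filters in the package use zero-padded history (a streaming
implementation with a cleared buffer), and the moving average is causal,
not centered: the offline evaluation re-aligns envelopes by
cross-correlation anyway, so a fixed group delay is harmless, and the
choice keeps the offline and streaming paths sample-for-sample comparable.

## Comparison denoisers

Two baselines bracket the comb on the cost/quality plane:

* **D-spaced integer comb** (`filter_dxn()`): subtracts the mean of `Nf`
  samples spaced `D` apart, $y(k) = x(k) - \frac{1}{N_f}\sum_i x(k-iD)$.
  With $D = f_s/f_\mathrm{pli}$ all taps are in phase at every multiple of
  $f_s/D$, so those components (and DC) are zeroed with a much higher
  quality factor than the two-tap comb - at the price of
  $D(N_f-1)+1$ stored samples (321 for the reference 20x17 setting),
  $N_f$ additions and one division per sample. The original publication of
  this baseline does not print its difference equation; this form is the
  unique simple integer-coefficient comb that reproduces both the published
  operation/memory counts and the stated zeros, and is adopted as such.
* **FFT block filter** (`fft_block_filter()`): transforms non-overlapping
  blocks, zeroes the bins of the powerline harmonics and of the 0-25 Hz
  band (conjugate partners included, so the output is real to machine
  precision), inverse-transforms. The 40-sample block at 1 kHz is the
  shortest transform whose 25 Hz resolution still puts every 50 Hz
  harmonic exactly on a bin. Block (not sliding) application is used: the
  short block length is precisely the design response to block-processing
  delay, and it keeps the filter exactly linear with fixed boundaries.
  Off-bin components (e.g. 12.5 Hz) leak and are only partially removed -
  a real limitation of the approach that the tests exercise deliberately.

`resource_profile()` returns the analytic cost of each algorithm, and
`instrument_filter()` re-derives the comb and D-spaced counts by actually
tallying the arithmetic in a scalar loop. FFT costs are reported as the
lower bound $(B/2)\log_2 B$ complex butterflies per transform (106 for
$B = 40$), the convention in which such costs are usually quoted; exact
counts depend on the FFT factorization and only strengthen the comparison.

## The synthetic corruption protocol

No public recording ships with the package, so `synth_*()` generators
define the study conditions. They are ordinary seeded functions - every
experiment is reproducible from (parameters, seed) - and they emulate:

* **clean sEMG** (`synth_emg()`): Gaussian noise band-passed to 20-450 Hz
  (4th-order Butterworth, forward-backward so zero-phase), amplitude-
  modulated by alternating rest/contraction segments. Rest sits at 0.05
  relative amplitude, contractions draw plateaus in [0.5, 1], segment
  durations in [0.5, 2] s, with 0.2 s raised-cosine transitions (a step
  profile smoothed by a Hann-weighted window, whose step response is a
  raised cosine). These are typical intermittent-contraction figures for
  forearm HMI use; the minimum sampling rate of 1 kHz keeps the 450 Hz
  band edge below Nyquist.
* **PLI** (`synth_pli()`): harmonics up to 500 Hz with $1/h$ amplitude
  decay and random fixed phases (an installation's true harmonic profile
  is idiosyncratic; $1/h$ is a generic nonlinear-load decay), optionally
  amplitude-modulated by a 0.5 Hz, depth-0.5 sinewave - a "slow"
  modulation relative to every EMG time scale.
* **motion artifacts** (`synth_artifact()`): Gaussian noise low-passed at
  4 Hz (4th-order, forward-backward), i.e. baseline wander concentrated
  well below the comb's 12.5 Hz cutoff; configurable up to 30 Hz for
  stress tests, where performance degrades by design.

`mix_at_snr()` defines SNR as the linear mean-square power ratio over the
whole record and scales the noise so the requested ratio holds *exactly*;
the protocol sweeps 0.05-10.

What the surrogate does **not** model: motor-unit action-potential
structure, electrode-skin impedance, nonstationary PLI frequency drift, or
brisk high-frequency artifact transients. Passing the recovery targets on
this surrogate therefore shows that the pipeline removes the modeled
nuisances without destroying burst-scale envelope morphology; it does not
certify third-decimal correlation values for any particular real
recording, which depend on that recording's noise profile.

## Evaluation protocol

`envelope_fidelity()` mirrors standard practice: compute the 88-sample
linear envelopes of the clean and processed records, drop a start-up
transient of `max(filter memory, envelope window) + 1000` samples (the
protocol leaves transient handling unstated; one extra second removes any
start-up bias at negligible data cost), re-align at the peak of the full
cross-correlation, and report the Pearson correlation of the overlap.
`correlation_gain()` is the ratio of filtered to noisy correlation - the
natural reading of "gain" for this quantity.

`run_sweep()` runs the full grid. Defaults: SNR grid
{0.05, 0.1, 0.2, 0.5, 1, 2, 5, 7, 10} (covering every named operating
point of the protocol), 30 s records at 1 kHz, five seeds per point to
quantify surrogate variability. The noise generator's seed is offset by
1000 from the EMG seed so the artifact surrogate never reuses the EMG
carrier's random draws. Typical behaviour, which the acceptance script
recomputes from scratch:

* flat or modulated PLI, comb-filtered: minimum correlation ≈ 0.99 across
  the whole SNR range (the matched comb cancels a stationary harmonic
  interference to numerical zero; modulation sidebands at ±0.5 Hz see a
  residual gain of only $2\sin(\pi N f_m/f_s) \approx 0.063$);
* motion artifacts, comb-filtered: ≥ 0.98 for SNR 1-10, dropping briskly
  below SNR 1 while the correlation gain stays above 2 down to SNR 0.2;
* the D-spaced comb matches the FFC within 0.02 on flat PLI (both null
  every harmonic exactly).

## Streaming integer pipeline

`stream_process()` emulates the microcontroller implementation exactly:
per input code, one ring-buffer comb subtraction, an absolute value, and
an accumulate; every 128 samples one right shift emits an envelope value.
The loop tallies its arithmetic - zero multiplications, zero divisions -
and the tally is part of the return value, so the headline claim is
checked on every run rather than asserted. Numerical contract: the
accumulator is bounded by $128 \times 1023 < 2^{17}$ for a 10-bit
converter (R doubles hold this exactly; a device needs ≥ 20-bit
intermediates), and the shift truncates toward zero, which equals floor on
the nonnegative accumulator, so the integer envelope sits within one code
*below* the floating block pipeline on identical input. Uniform sampling
is a precondition of the whole construction - the comb nulls are defined
in samples, not seconds - and is the stream contract's stand-in for the
hardware timer requirement. Serial transport and board I/O are out of
scope.

`adc_emulate()` provides the unipolar converter model (floor quantization
to $2^\mathrm{bits}$ codes with clipping counted, not fatal). The comb's
zero DC gain is what makes the unipolar offset harmless: no reference
subtraction is needed before rectification.

## Numerical and design choices

* **Tolerances.** Null/cutoff boundary comparisons use 1e-9 Hz; a null
  exactly at the requested `f_max` is included. Cancellation assertions
  use 1e-9 RMS (measured residuals are ~1e-13, i.e. double-precision
  round-off).
* **Degenerate inputs.** Correlation and alignment reject constant series
  rather than returning NaN; `ma_cutoff_hz(1, fs)` is an error (an
  all-pass has no cutoff); a trailing partial FFT block passes through
  with a warning rather than being silently dropped or zero-padded.
* **Problem sizes.** The shipped tests exercise the full protocol (30 s,
  five seeds) for the headline recovery numbers and 5-10 s records for
  structural properties; these sizes reproduce the protocol's operating
  points while keeping the suite fast.
* **Known limitations.** Single-channel only; no adaptive tracking of a
  drifting mains frequency (the nulls are fixed by `N`); artifact energy
  inside the comb passbands (brisk movements) is not removed; the
  surrogate generators bound what the recovery numbers can claim about
  real recordings (see above).
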