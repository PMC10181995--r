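# emgcomb

Powerline-interference and motion-artifact removal for surface EMG with a
feed-forward comb filter, plus multiplication-free linear-envelope
extraction — the denoising front end a human–machine interface needs before
it can trust an EMG envelope, at the cost of one subtraction per sample.

## Who this is for

Anyone extracting the EMG linear envelope (EMG-LE) on resource-constrained
hardware, or benchmarking lightweight EMG denoisers offline: biomedical
signal-processing researchers, HMI/prosthetics developers, and embedded
engineers who need to know exactly how many operations a filter costs.

## The method

The feed-forward comb (FFC) filter is

```
y(k) = x(k) + α·x(k − N),      α = −1 for cancellation
```

with amplitude response `H(f_n) = 2|sin(πN f_n)|` (`f_n = f/f_s`): nulls at
every multiple of `f_s/N` **including DC**, peak gain 2, and −3 dB cutoffs
at `(1/4 + k)·f_s/N` and `(3/4 + k)·f_s/N`. Setting `N = f_s/f_pli`
(N = 20 at 1 kHz for 50 Hz mains) puts a null on the powerline fundamental
and on every harmonic, while the zero DC gain and the 12.5 Hz first cutoff
simultaneously remove offset voltages and low-frequency motion artifacts —
all with a single subtraction and 20 stored samples. Rectification and an
88-sample moving average (−3 dB at 5.03 Hz) then give the envelope; with a
power-of-2 window (128 samples) even the averaging division becomes a bit
shift, so the whole streaming pipeline runs without one multiplication.

The package also provides two comparison denoisers (an integer D-spaced
comb, `filter_dxn()`, and an FFT block filter with spectral-bin
cancellation, `fft_block_filter()`), per-algorithm operation/memory
accounting (`resource_profile()`, confirmed by instrumented runs), seeded
generators for surrogate EMG/interference/artifacts, an SNR-sweep
evaluation protocol (`run_sweep()`), and an integer-only streaming
emulation of the microcontroller pipeline (`stream_process()`).

## Worked example

Corrupt a 30 s surrogate EMG with harmonic powerline interference twenty
times stronger than the signal (SNR 0.05), filter with the matched comb,
and score envelope recovery:

```r
library(emgcomb)
fs <- 1000
clean <- synth_emg(30, fs, seed = 1)
pli   <- synth_pli(30, fs, pli_spec(f0 = 50, seed = 1001))
noisy <- mix_at_snr(clean, pli, snr = 0.05)$mixed

comb     <- ffc_params(ffc_delay(fs, 50), alpha = -1, fs = fs)
filtered <- ffc_apply(noisy, comb)

envelope_fidelity(clean, noisy)     # Pearson r of noisy envelope
envelope_fidelity(clean, filtered)  # ... and of the recovered envelope
```

Output:

```
noisy    r = 0.493
filtered r = 0.994
gain       = 2.0
<ffc_params> N = 20, alpha = -1, fs = 1000 Hz
  nulls every 50 Hz (incl. DC); first -3 dB cutoff 12.5 Hz
<resource_profile> ffc: 1 add, 0 mult, 0 div per sample; 20 samples stored
```

Under noise 20× stronger than the EMG, the corrupted envelope correlates
only 0.49 with the truth; after the one-subtraction comb it correlates
0.99. The last line is the filter's entire computational budget.

A command-line front end over the same functions ships at
`system.file("cli", "emgcomb", package = "emgcomb")`, with `simulate`,
`filter`, `envelope`, `stream` and `evaluate` subcommands (single-channel
CSV with a `# fs=<Hz>` header as interchange format).

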