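Package: emgcomb
Title: Feed-Forward Comb Filtering and Linear-Envelope Extraction for Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for removing powerline interference and motion artifacts from
    surface electromyography (sEMG) with a feed-forward comb (FFC) filter, and for
    extracting the EMG linear envelope by full-wave rectification and moving-average
    smoothing. Includes closed-form analysis of the comb amplitude response (nulls
    and -3 dB cutoffs), two comparison denoisers (an integer-coefficient comb with
    D-spaced taps and an FFT block filter with spectral-bin cancellation),
    per-algorithm arithmetic and memory resource accounting, seeded generators for
    surrogate EMG, powerline interference and baseline-wander artifacts, an
    SNR-sweep evaluation protocol based on cross-correlation re-alignment and
    Pearson correlation of envelopes, and an integer-only streaming emulation of a
    microcontroller envelope pipeline that uses no multiplications or divisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
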