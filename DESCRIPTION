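Package: eegstream
Title: Mobile EEG Telemetry: Adaptive Delta Codec, IIR Filter Bank and
    Alpha-Paradigm Validation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software model of a 24-channel mobile EEG acquisition and
    telemetry path: a 24-bit ADC front end with programmable gain, an
    adaptive delta-encoding (ADPCM-style) codec with per-channel bit shift
    and safety factor, a Butterworth IIR filter bank with decimation, a
    lossy ordered packet channel with loss monitoring, a synthetic
    eyes-open/eyes-closed EEG generator, and the validation analysis
    (epoching, multitaper power spectra, cluster-based permutation
    statistics) that recovers the occipital alpha contrast from the
    synthetic recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    data.table,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
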