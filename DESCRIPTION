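Package: mritexture
Title: Texture-Based Quality Auditing of Grayscale MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for objective, region-of-interest based quality
    comparison of grayscale magnetic resonance images. Implements
    first-order histogram texture features, Haar wavelet subband
    energies, a focus index (skewness-to-kurtosis ratio) with a noise
    retention filter, a dispersion index (variance-to-mean ratio),
    bit-depth auditing of DICOM pixel data (measured versus reported
    stored bits), 16-bit to 8-bit least-significant-bit degradation, a
    between-class/within-class feature-selection coefficient with
    control-point injection and leave-one-out 1-nearest-neighbour error,
    and pooled two-sample group statistics. A synthetic labeled brain
    phantom generator emulating 1.5 T and 3 T acquisition presets
    replaces patient data, and a command-line front end drives
    reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    e1071,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
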