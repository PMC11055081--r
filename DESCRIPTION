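Package: drowsEEG
Title: Drowsiness Scoring from Eye Aspect Ratio and EEG Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating video-based drowsiness scoring against
    electroencephalography. Detects eye blinks and closures from eye-aspect-ratio
    (EAR) traces with an adaptive median/moving-average threshold, scores
    alternating wakefulness/drowsiness episodes from PERCLOS and closure
    duration, extracts ten spectral and wavelet EEG features per episode and
    channel (band powers, band-power ratios, spectral entropy, spread, centroid
    and rolloff), labels episodes as concordant between the two modalities, and
    summarises per-channel, per-region and all-channel sensitivities across a
    cohort. Includes a seeded simulator producing coupled EAR and six-channel
    EEG sessions with ground-truth episode structure, and readers/writers for
    EDF and delimited-text representations of every intermediate product.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
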