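Package: livesort
Title: Live Spike Sorting by Streaming Template Matching Pursuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Streaming spike sorting of multichannel extracellular
    recordings by template matching pursuit: offline template learning on a
    training segment, batched online preprocessing (common median reference,
    FFT high-pass, spatial whitening), iterative spike detection and
    subtraction against a learned template bank, spike localization and
    cluster assignment.  Includes a ground-truth recording simulator with
    direction-tuned units, a validation suite (spike-train agreement
    scores, PSTH and von Mises tuning comparison, population decoding,
    neuron-dropping curves with saturating-exponential asymptote fits), and
    a closed-loop paradigm that triggers stimulus events on the live-sorted
    firing rate of fast-spiking units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
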