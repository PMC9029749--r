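Package: roarid
Title: Individual Identification of Lions from Roar Acoustics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A workbench for individual vocal identification of African lions
    from full-throated roars. Audio clips are rendered into eight
    time-frequency image representations (power spectrogram, Mel spectrogram,
    the iterated-log LM/L2M/L3M family, MFCC, a decimated Stockwell
    transform, and a 128-dimensional embedding-over-time image), classified
    with pluggable image backbones, fused by sum-rule ensembling, and
    evaluated under grouped leave-one-out designs (recording day, roar bout)
    and a one-vs-many Equal Error Rate protocol. A seeded synthetic roar
    generator emulates the grouping structure of field datasets so the whole
    pipeline is testable without field recordings.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
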