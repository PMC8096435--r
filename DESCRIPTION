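Package: blastoquant
Title: Multiscale Quantification of Mouse Preimplantation Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification toolbox for mouse preimplantation development
    imaged at nested timescales. Provides two-pass cross-correlation particle
    image velocimetry (PIV) for short-timescale movies of cortical
    contractions, Fourier power-spectrum analysis with a band-limited
    oscillation call, compaction and growth morphometrics (contact angles,
    ellipse fits, projected-area growth rates), cleavage-wave event logic,
    immunofluorescence nuclear-to-cytoplasmic quantification, the matching
    statistical toolbox, and a synthetic-data generator with genotype presets
    so the full pipeline can be exercised and validated without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
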