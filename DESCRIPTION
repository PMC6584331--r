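Package: mycotrade
Title: Quantum-Dot Tracing of Phosphorus Trade in Mycorrhizal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis stack for tracking fluorescently tagged
    phosphorus (quantum-dot apatite) through arbuscular mycorrhizal fungal
    networks: linear spectral unmixing of quantum-dot emission from tissue
    autofluorescence with calibration to specific uptake, raster image
    correlation spectroscopy (RICS) for counting particles per observation
    volume and converting to hyphal retention, single-particle tracking of
    intra-hyphal flows with a zero-truncated normal mixture decomposition of
    speeds, an analytic Stokes-Einstein advection-versus-diffusion transport
    model, and compartment-level trade and translocation accounting. Includes
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
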