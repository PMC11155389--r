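Package: pactrecon
Title: Delay-and-Sum and Filtered Back-Projection Reconstruction for
    Photoacoustic Computed Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Configuration-driven reconstruction of three-dimensional
    photoacoustic computed tomography (PACT) volumes from raw
    time-resolved transducer signals.  Implements solid-angle-weighted
    delay-and-sum (DAS) and filtered back-projection (FBP) beamforming
    over arbitrary detector arrays (scanned planar apertures and
    Fibonacci-lattice hemispheres), depth-slab partitioned parallel
    reconstruction, an analytical N-wave forward simulator for spherical
    absorbers, and postprocessing (rectification, Hilbert envelope
    detection, normalization, maximum-intensity projection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    yaml,
    signal,
    jsonlite,
    png,
    parallel,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
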