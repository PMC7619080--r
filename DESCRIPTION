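Package: thetasweeps
Title: Coupled Attractor Network Model of Theta Sweeps in Head-Direction and
    Grid Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a coupled continuous-attractor model of theta-modulated
    head-direction cells (ring attractor) and grid cells (toroidal attractor)
    with firing rate adaptation and speed-scaled medial-septal theta
    modulation. The model intrinsically generates left-right-alternating theta
    sweeps of internal direction and internal location. The package bundles
    synthetic trajectory generators, decoding of bump centers from the torus
    back to physical space, per-theta-cycle sweep statistics (sweep angle,
    length, alternation score), and single-cell spike-train statistics
    (autocorrelograms, theta-cycle-skipping index, directional tuning width,
    circular-linear phase precession), together with a parameter sensitivity
    analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
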