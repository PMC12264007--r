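Package: spinefusi
Title: Functional Ultrasound Analysis of Spinal Cord Hemodynamics During
    Urodynamic Bladder Filling and Emptying
Version: 0.1.0
Authors@R:
    person("spinefusi", "developers", email = "spinefusi@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse power-Doppler (pD) functional ultrasound
    image time series of the spinal cord acquired during urodynamically
    controlled bladder filling and emptying. Provides SVD clutter
    filtering of compound frame blocks, phase-correlation sub-pixel
    motion registration and rigid correction, zero-phase FIR lowpass
    filtering, percent signal change relative to a pre-filling baseline,
    pixel-wise Pearson activation mapping with Benjamini-Hochberg false
    discovery rate control, and a transductive linear epsilon-insensitive
    support vector regression that reconstructs intravesical bladder
    pressure from pD pixels.  A fully seeded synthetic-data generator
    emulates the urodynamic protocol (pressure trace, phantom stacks with
    planted pressure-coupled regions, rigid motion, compound blocks) so
    every stage is testable by parameter recovery without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
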