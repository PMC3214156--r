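Package: fiberprobe
Title: Geometric Modelling of Fiber-Optic Probe Illumination and
    Collection Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form geometric model of the illumination and collection
    efficiency of fiber-optic probes used in biomedical reflectance,
    fluorescence and Raman spectroscopy, as a function of probe-sample
    distance, tilt angle, fiber core size, numerical aperture and
    inter-fiber spacing.  Includes a deterministic optimizer for the
    optimal probe-sample distance of multi-fiber probes, seeded
    Monte-Carlo geometric oracles that validate the closed forms, a
    fluorescence-spectra toolkit (band integration, distance-series
    optimum location) and a synthetic skin-autofluorescence generator
    driven by the efficiency model.  A command-line interface regenerates
    all model curves as delimited tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
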