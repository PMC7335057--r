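Package: pupilbench
Title: Benchmarking Classical Luminance-Based Pupil Light Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate how well classical L- and M-cone (luminance)
    based pupil diameter models predict measured pupil light responses under
    chromatic and polychromatic stimuli. Provides the eight closed-form pupil
    models (Holladay, Crawford, Moon & Spencer, De Groot & Gebhard,
    Stanley & Davies, Barten, Blackie & Howland, Watson & Yellott) with
    adaptation-field angle conversions, spectral stimulus characterization
    (luminance, chromaticity, correlated color temperature, alpha-opic
    radiances), pupillometry trace preprocessing (blink and quality filtering,
    velocity-percentile outlier rejection, interpolation, Savitzky-Golay
    smoothing), prediction-error benchmarking with repeated-measures ANOVA,
    and a seeded synthetic cohort generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    pracma,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
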