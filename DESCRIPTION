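Package: nlcontrast
Title: Second-Order Nonlocal Contrast Maps and Aperture Stimulus Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-computable model of second-order (filter-rectify-filter)
    visual mechanisms. Computes multi-scale maps of nonlocal contrast modulation
    amplitude with a sliding center-surround operator whose band-pass center
    energy is compared against octave-averaged surround power, selects
    non-overlapping regions of maximum, medium and minimum modulation amplitude,
    and recombines them through Gaussian apertures into "bubbles"-style stimuli
    for face and object recognition experiments. Includes the companion
    statistics layer for between-subjects accuracy data: one-way ANOVA with
    Brown-Forsythe and Welch heterogeneity corrections, Levene's test, partial
    eta squared and Cohen's f, Tukey/Bonferroni/Holm post hoc comparisons, and
    exact binomial confidence intervals, plus deterministic synthetic fixtures
    (modulated textures, schematic faces, simulated response logs) with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    utils,
    car,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
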