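Package: oilspec
Title: Multi-Modal Spectroscopic Detection and Quantification of Edible Oil
    Adulteration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, fusion and chemometric evaluation of
    fluorescence excitation-emission, near-infrared and Raman spectra of
    edible oil blends, aimed at detecting and quantifying adulteration of
    chia oil with cheaper seed oils. Provides designed blend tables,
    a parametric endmember spectra generator with instrument noise,
    derivative-cumsum baseline correction and standard normal variate
    scaling, low-level three-block data fusion, class-balancing spectra
    augmentation, five-way classification (decision tree, regularized
    linear discriminant, nearest neighbour, linear and cubic support
    vector machines) with repeated-run summaries, and partial least
    squares regression of adulteration level with leave-one-out
    cross-validation, range-normalized prediction error and three-sigma
    detection limits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
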