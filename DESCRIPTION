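Package: petkin
Title: Compartmental Kinetic Modeling of Dynamic PET Time-Activity Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pharmacokinetic quantification of dynamic positron emission
    tomography (PET) data from regional time-activity curves and arterial
    input functions. Implements plasma-input compartment models (one- and
    two-tissue), spectral analysis with non-negative exponential
    decomposition, and reference-tissue models (SRTM, FRTM, and a simplified
    reference tissue model with a two-compartment reference region), together
    with AIC-based model preference, Bland-Altman agreement statistics, and a
    fully specified three-tissue-compartment simulation study for evaluating
    model behaviour across binding levels and noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
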