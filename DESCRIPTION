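Package: dspi
Title: Diurnal Saturated Photosynthesis from Rapid Light Curves and
    Irradiance Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the irradiance-normalized Webb photosynthesis-irradiance
    model to PAM rapid light curves (alpha, E_k, P_max, rETR_max), processes
    minute-resolution PAR logger traces into day length and daily time in
    saturating irradiance (H_sat) with period-mapped E_k, computes the
    diurnal saturated photosynthesis index (DSPI = P_max x H_sat, mol m-2)
    and 9-day wet-weight growth, and relates them with linear mixed-effects
    models, likelihood-ratio tests and Nakagawa-Schielzeth R2. Includes a
    synthetic-study generator emulating a salinity/nutrient x temperature
    macroalgal experiment so the whole pipeline is testable without
    instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
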