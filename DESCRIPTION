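Package: abscissr
Title: Directional Seed Abscission Mechanics for the Dandelion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the direction-dependent force required to detach (abscise)
    dandelion seeds from the receptacle. The attachment is treated as a
    two-material cantilever: the porous pedicle plus the engaged, horseshoe-shaped
    attachment-site tissue bend as one transformed (modulus-weighted) section,
    so the neutral axis, second moment of area and outer-fibre distance differ
    between pulls toward the capitulum apex and pulls toward the scape.
    Provides the resulting abscission force-ratio predictions, fitting of the
    pedicle-to-base stiffness ratio against measured force ratios, sensitivity
    sweeps over attachment geometry, robust summaries of load-cell force data
    (medians, interquartile ranges, percentile-bootstrap confidence intervals,
    Wilcoxon rank-sum tests), a calibrated log-normal generator of synthetic
    force measurements, and an end-to-end reproducible analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
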