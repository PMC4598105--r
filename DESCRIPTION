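Package: nichelumps
Title: Self-Organized Body-Size Lumps in Competitive Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the self-organization of competing species
    into regularly spaced body-size groups ("lumps"). Provides a
    Lotka-Volterra niche-competition simulator with evolving trait
    positions, Gaussian-mixture and kernel-density mode detection for log
    body-size distributions, a co-occurrence pairwise body-length-ratio
    pipeline, and seeded synthetic-data generators that emulate species
    catalogues and field occurrence samples. Results are returned as
    tibbles with broom-style tidy() and glance() methods and ggplot2
    autoplot() methods.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
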