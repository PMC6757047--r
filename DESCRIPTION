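Package: semioprofile
Title: Chemical Profiling of Scent-Mark GC-MS Peak Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for deconvoluted GC-MS peak lists from mammalian
    scent samples: per-batch retention-time adjustment, gap-based grouping of
    peaks into retention-time ranges, occurrence filtering, prominent-mass
    extraction with an automated spectral-consistency check, contaminant and
    blank exclusion, relative peak areas, ANOSIM with restricted permutations
    that respect repeated sampling of individuals, and a vectorised linear
    mixed-model screen that flags the substances most affected by ovarian
    cycle state, age and parity. A synthetic-data module generates complete
    studies (peak lists, blanks, contaminants, planted effects) with a
    recorded ground truth so every stage is testable without instrument data.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
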