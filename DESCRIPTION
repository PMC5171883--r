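Package: linedrift
Title: Drift Tests for Divergence Between Artificial Selection Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a trait difference between a selected
    line and its unselected control reflects a correlated response to
    selection or merely genetic drift. Computes standardized line divergences
    (D_y) from published group summaries (means, SEMs, group sizes), builds
    the 95% drift interval from the pedigree inbreeding coefficient (F),
    trait heritability (h2) and the number of families (n), and flags traits
    whose divergence exceeds it. Includes pedigree reading and exact
    inbreeding coefficients (Meuwissen-Luo), scoring of Go/No-go operant
    sessions, Y-maze spontaneous alternation and rotarod endpoints from raw
    records, and a within-family selection breeding simulator under the
    infinitesimal model used to verify the statistical calibration of the
    drift test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
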