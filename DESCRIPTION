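Package: piefm
Title: Elementary Flux Mode Extraction by LP Seeding and Simplex Pivoting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting elementary flux modes (EFMs) from
    constraint-based metabolic network models. Implements the PiEFM
    algorithm, which seeds an EFM collection with randomly weighted linear
    programs and then expands it by post-optimal simplex pivoting to
    adjacent vertices of the flux cone; an exact double-description
    enumerator and a brute-force oracle for small networks; a suite of
    representativeness and stability metrics for judging how well a biased
    EFM sample reflects the full set (mean-length traces, per-reaction
    proportions, mean relative error, d-offset stability with a stopping
    rule, reaction compatibility and coupling analysis); loaders for SBML
    Level 3 (FBC), BIGG JSON and a plain TSV network dialect; and
    deterministic synthetic network generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    generics,
    jsonlite,
    xml2,
    ggplot2,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
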