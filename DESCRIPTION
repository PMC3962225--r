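Package: csmtools
Title: Compound Promiscuity Analysis and Compound Series Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mining multi-target activity spaces of small molecules:
    curation of Ki/IC50 activity tables, per-compound target profiles and
    promiscuity statistics (global, per target family, per molecular-weight
    bin), matched molecular pair (MMP) generation with transformation size
    restrictions, promiscuity-cliff detection and cliff networks,
    shared-compound target co-activity networks and drug-target bipartite
    networks, and two-step Compound Series Matrix (CSM) construction with
    virtual-compound enumeration for design. Includes a synthetic-fixture
    generator producing analog series with planted cores, substituents and
    target profiles for fully reproducible, database-free analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
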