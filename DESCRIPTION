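Package: episwarm
Title: Particle Swarm Search for SNP-SNP Interactions in Case-Control Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects K-way SNP-SNP interactions (epistasis) in case-control
    genotype data with a discrete particle swarm optimizer enhanced by
    opposition-based learning, a counter-driven dynamic inertia weight, and an
    exhaustive post-search over the most frequently visited SNPs. Fitness is
    the plug-in mutual information between a SNP combination and the binary
    phenotype, with a likelihood-ratio (G) test for reporting. Includes a
    penetrance-model case-control simulator with Hardy-Weinberg background
    SNPs and a detection-power (Power 1 / Power 2) benchmarking harness, plus
    a plain-PSO baseline for comparison.
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
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
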