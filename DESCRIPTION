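Package: gmcsr
Title: Genetic Minimal Cut Sets in Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes genetic minimal cut sets (gMCSs): inclusion-minimal sets
    of genes whose simultaneous knockout blocks a target metabolic task (the
    biomass reaction) in a constraint-based metabolic model. Gene-protein-
    reaction boolean rules are compiled into a gene-knockout matrix, gMCSs
    containing a designated target gene are enumerated by solving a dual-
    problem mixed-integer linear program with integer cuts, and every solution
    is verified and shrunk to inclusion minimality by explicit linear-
    programming checks. Gene-expression z-score tables are used to classify
    lowly expressed genes and to issue per-sample gene-essentiality verdicts
    (a gene is predicted essential when some gMCS contains it with all partner
    genes lowly expressed), and the accompanying statistics layer provides
    contingency-table odds ratios from logistic regression, one-sided binomial
    frequency tests, partner-expression sensitivity analyses (Spearman,
    Mann-Whitney) and false-discovery-rate adjustment. Includes SBML and
    COBRA-style JSON model input, deterministic toy fixtures with oracle-known
    answers, and a brute-force enumeration oracle for validation on small
    networks.
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
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
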