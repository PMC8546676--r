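Package: perihg
Title: Mercury Methylation Kinetics and Methylator Community Screening in Periphyton
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for isotope-tracer mercury transformation assays
    in periphyton and the associated microbial community data. Estimates
    first-order methylation and demethylation rate constants from enriched
    stable-isotope (Hg-200 / MM-Hg-198) single-time-point incubations with
    detection-limit censoring, summarises replicates and compares sites by
    ANOVA; performs mercury speciation bookkeeping (inorganic Hg by
    subtraction, percent monomethylmercury, ash-free dry weight fractions,
    spike-to-ambient fold ratios); screens predicted proteins for the HgcA
    methylation protein using bit-score thresholds and conserved cap-helix
    motifs with coverage-weighted abundance; assigns taxonomy by similarity
    best-hit and phylogenetic clade placement with a consensus agreement
    statistic; and profiles 16S amplicon sequence variant tables (relative
    abundance, rare-taxon lumping, Bray-Curtis, principal-coordinate analysis,
    PERMANOVA). A synthetic-data module generates every input with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    ape,
    vegan,
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
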