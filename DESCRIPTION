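Package: camba
Title: Coverage-Aware Bayesian Mutation Calling from Overlapping DNA Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls rare induced point mutations, and the wells that carry
    them, from deep-sequenced bi-dimensionally overlapping DNA pools as used
    in TILLING (Targeting Induced Local Lesions IN Genomes) reverse-genetics
    screens. Each individual's DNA is present in exactly one row pool and one
    column pool of a 96-well plate; the caller scores every candidate
    configuration (no mutation, or one mutant well with a specific base
    change and zygosity) with a binomial sequencing-error model and
    mutagenesis priors, and reports the posterior probability of each call.
    Includes the quality, coverage and strand-orientation pre-filters, the
    expected-mutation threshold selection procedures, a z-score outlier
    comparator, scaled confusion-matrix evaluation, and a synthetic pooled
    experiment simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
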