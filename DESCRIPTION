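Package: mtdrive
Title: Selfish Replicative Drive and Drift of Mitochondrial DNA Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of intracellular mitochondrial
    DNA (mtDNA) heteroplasmy under genetic drift, recurrent mutation and
    selection during organellar turnover; coverage-dependent variant-detection
    modelling for single-cell sequencing; per-allele summary statistics (cell
    count C# and average allele abundance AAA); cohort threshold rules for
    calling replicative-drive ("driver") alleles; grid-search inference of
    mutation rate and selection coefficient by permutation matching of
    per-cell abundance distributions; tissue-level accumulation fitting
    (linear versus power growth); driver-passenger linkage analysis; and a
    synthetic single-cell mutation-table generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
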