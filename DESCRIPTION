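Package: gametecross
Title: Crossover Detection and Recombination Traits from Single Gamete Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for meiotic recombination measured in single
    haploid gametes (e.g. flow-sorted pollen nuclei genotyped on a SNP array).
    Phases the two parental haplotypes of each diploid individual from its
    gametes by majority voting, aggregates haplotype origins into relative
    chromosomal windows, calls crossovers as haplotype switches under a gap
    rule, and derives per-individual crossover traits: crossover count per
    chromatid, crossover interference distance, and intrachromosomal genetic
    shuffling (r-bar intra). Includes broad-scale recombination landscapes in
    cM/Mb, group comparisons (ANOVA with Tukey's HSD, per-window chi-square
    tests with FDR correction, beneficial-allele stacking), and a meiosis
    simulator with crossover interference modelled as a stationary gamma
    renewal process, providing ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
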