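Package: rfmap
Title: Fine Mapping of a Dominant Restorer-of-Fertility Locus from F2 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping a single dominant restorer-of-fertility (Rf)
    locus segregating in an F2 population, as used in pepper (Capsicum
    annuum) three-line hybrid breeding. Implements chi-square tests of
    fertile:sterile segregation ratios, in-silico bulked segregant analysis,
    recessive-class recombination-fraction estimation with Kosambi genetic
    distances, flanking-marker interval localization, candidate-gene
    variant-effect classification and variant-trait concordance scoring
    across maintainer and restorer lines, relative expression analysis of
    qRT-PCR Ct tables by the 2^-ddCt method, and InDel marker discovery
    from pairwise genome sequence comparison. A synthetic-data module
    simulates F2 meiosis under the Haldane model, inbred-line allele
    matrices, Ct tables, and planted-indel sequence pairs so every stage is
    testable without external data; transcriptions of the published marker
    and segregation tables ship as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
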