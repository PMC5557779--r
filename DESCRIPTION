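Package: bsamap
Title: Bulked Segregant Analysis Mapping with Pooled Allele Depths
Version: 0.1.0
Authors@R:
    person("bsamap", "developers", email = "bsamap@example.org",
           role = c("aut", "cre"))
Description: Association mapping from bulked segregant analysis (BSA)
    sequencing of two phenotype pools and their parents. Implements
    marker screening of per-site allele depths, the SNP-index and
    delta(SNP-index) statistics, the Euclidean-distance (ED) allele
    frequency statistic with its fifth power, sliding-window averaging,
    local linear (loess) smoothing with AICc span selection,
    threshold-based candidate-region calling and region intersection,
    recombinant-based fine mapping of homozygous-recessive F2 plants
    (Kosambi map distances, segregation tests), and a synthetic F2
    bulk-sequencing generator so the whole pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
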