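Package: domestiscan
Title: Domestication-Selection Scans on Duplicated Rice Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic analysis of duplicated crop loci contrasted
    between cultivated and wild germplasm panels. Provides per-locus and
    sliding-window diversity statistics (segregating sites, nucleotide
    diversity, Watterson's theta, Tajima's D, haplotype typing), the
    Hudson-Kreitman-Aguade neutrality test against a reference locus,
    Nei-Gojobori Ka/Ks estimation with molecular-clock duplication dating,
    neighbor-joining trees with gene-tree versus genome-tree incongruence
    measures, flanking-gene colinearity detection, and a seeded coalescent
    simulator of the cultivated/wild sampling design (bottleneck, selective
    sweep, introgression) so every stage can be exercised and calibrated at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
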