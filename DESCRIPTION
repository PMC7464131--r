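Package: karyoanchor
Title: Physical-Map Integration for Chromosome-Scale Genome Anchoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates BAC clone placements and BAC-FISH cytogenetic
    assignments with scaffold-level genome assemblies to anchor scaffolds
    to chromosomes, detect chimeric scaffolds (misjoins spanning two or
    more chromosomes), reconcile chromosome nomenclature between an
    assembly and a karyotype by consensus voting, and summarise
    cross-species chromosome homology from filtered and chained synteny
    blocks and marker gene orders. Includes a truth-known synthetic data
    generator (karyotypes, fragmented assemblies with induced misjoins,
    BAC clones, rearranged partner genomes) for validating every step,
    plus assembly contiguity statistics (N50/L50) and circos/dot-plot
    exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
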