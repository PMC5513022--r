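Package: lignoreg
Title: Lignin-Pathway Candidate Gene Discovery from qPCR, miRNA Target and
    Promoter Motif Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for identifying lignin-pathway candidate genes
    and their regulation in flax-like datasets. Implements reference-gene
    (qBase-style) normalization of high-throughput RT-qPCR quantification
    cycles with exact Mann-Whitney differential calls, k-means-medians
    co-expression clustering under Pearson correlation distance, rule-based
    plant miRNA target prediction with wobble-aware penalty scoring and
    cleavage-site mapping from RLM-RACE fragments, degenerate IUPAC scanning
    of proximal promoters for MYB cis-elements (MBS/MBSIIG), and an
    evidence-combining candidate prioritizer. A synthetic-data generator
    emits every input format with a ground-truth manifest so that each stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    mclust,
    withr,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
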