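Package: cpseq
Title: Analysis Pipeline for 2',3'-Cyclic-Phosphate RNA Sequencing
Version: 0.1.0
Authors@R: person("cpseq", "maintainers", email = "cpseq@example.org",
    role = c("aut", "cre"))
Description: Tools for the informatic analysis of 2',3'-cyclic-phosphate RNA
    sequencing (cP-RNA-seq) libraries: 3'-adapter trimming and length
    selection, prioritized sequential mapping of short reads to spike-in,
    tRNA, rRNA, mitochondrial, mRNA and genome references with a bounded
    Hamming distance, classification of tRNA-mapped reads into the
    half/tRF taxonomy (including histidine -1 variant calling),
    terminal and flanking nucleotide-composition analysis of the C|A
    cleavage signature, anticodon-loop cleavage-site inference, and
    spike-in-normalized RPKM fold-change comparison between conditions.
    A ground-truthed read simulator emulating endonucleolytic C|A
    cleavage supports property-based validation of every stage.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
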