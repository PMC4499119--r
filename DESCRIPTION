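Package: bscapture
Title: Bisulfite Capture Sequencing Toolkit: Probe Design, Methylation
    Calling, Allelic Assignment and 5hmC Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for convert-then-capture bisulfite sequencing assays:
    bisulfite-aware hybridization capture probe design (four panels covering
    both strands and both CG-methylation assumptions), per-cytosine
    CG/CHG/CHH methylation calling with capture quality-control metrics,
    bisulfite-informative SNP filtering with parent-of-origin read
    assignment for hybrid samples, TAB-seq based 5-hydroxymethylcytosine
    quantification, methylation-based target-region classification, and a
    deterministic simulator producing genomes, diploid parents, methylomes
    and paired-end bisulfite/TAB-seq reads with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
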