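Package: cffrag
Title: Cell-Free DNA Fragmentomics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for low-coverage cell-free DNA (cfDNA)
    fragmentomics, with an emphasis on salivary cfDNA. From aligned,
    deduplicated fragments (BAM/SAM or fragment TSV) it builds
    fragment-length histograms and the jagged peak-valley index, tiles the
    genome into megabase bins with per-bin coverage and short/long fragment
    scores, profiles 4-mer fragment end motifs with Shannon entropy, scans
    for G-quadruplex motifs, quantifies the mitochondrial read fraction,
    relates fragments to peak calls and genomic-element annotations,
    summarises microbial taxa tables (relative abundance and alpha
    diversity), and integrates per-sample features across a two-group
    cohort with Welch t tests, two-stage Benjamini-Krieger-Yekutieli FDR
    control, ROC/AUC and principal component analysis. A synthetic-cohort
    generator with planted group effects makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    vegan,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
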