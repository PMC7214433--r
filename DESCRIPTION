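Package: capiso
Title: Targeted Full-Length Isoform Capture Sequencing: Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale analysis toolkit for targeted long-read isoform
    sequencing experiments in which hybridization probes derived from a single
    ORF per gene enrich full-length cDNA.  Provides a synthetic-data generator
    with known ground truth (genome, multi-isoform annotation, wide
    dynamic-range expression, overlap-dependent capture, barcoded full-length
    reads with PCR chimeras, short-read junction coverage), probe
    capture-coverage estimation, full-length read processing with dual-barcode
    chimera detection, SQANTI-style structural classification of isoforms
    (FSM/ISM/NIC/NNC), functional feature annotation (CAGE support, polyA
    motifs, splice-site conservation), orthogonal short-read junction
    validation, enrichment statistics and saturation-discovery curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
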