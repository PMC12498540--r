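Package: riboMeth
Title: Quantification and Differential Analysis of rRNA 2'-O-Methylation
    from RiboMeth-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying ribose 2'-O-methylation on 18S and 28S
    ribosomal RNA from RiboMeth-Seq alkaline-hydrolysis fragment data.
    Implements per-position 5'/3' read-end counting from alignments,
    shift-and-combine cleavage profiling, the score C methylation index
    at a catalogue of known modified positions, replicate aggregation,
    and the differential-methylation statistics used to compare cell
    states (unpaired equal-variance t-tests, one-way ANOVA with Tukey's
    multiple-comparison test, hyper/hypo classification, hypomethylated
    site selection). Also provides qPCR-side scores (RTL-P methylation
    index, serial-dilution standard curves, arbitrary snoRNA copy
    numbers, immunoprecipitation enrichment) and a seeded fragment-end
    simulator that supplies ground truth for every stage. Ships a
    reference methylation dataset for human embryonic stem cells, neural
    stem cells and neurons in wild-type and FMR1 knockout backgrounds.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
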