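Package: hetkaryo
Title: Detection of Within-Isolate Genetic Variation in Heterokaryotic Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterise within-isolate nuclear genetic
    variation in coenocytic fungi such as arbuscular mycorrhizal fungi, where
    a single individual may carry two genetically different nucleus genotypes
    (a heterokaryon). Implements in silico double-digest RADseq (EcoRI/MseI)
    fragment prediction, repeated-element labeling by three complementary
    methods, per-sample poly-allelic site classification from read pileups or
    VCF with depth/frequency/quality filters, bi-allelic site density and
    allele-frequency distributions with coverage-threshold sweeps, replicate
    concordance with cumulative hypergeometric overlap tests, reference-free
    discovery of bi-allelic transcript positions via De Bruijn graph SNP
    bubbles with codon-effect prediction, and RNA-to-genome allele-composition
    consistency classification. A seeded synthetic heterokaryon data generator
    (two haplotypes mixed at a nucleus ratio p, with WG, ddRAD and RNA reads
    plus truth tables) makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
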