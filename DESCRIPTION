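Package: avenacomp
Title: Comparative Genomics of Diploid Oat Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the comparative-genomics analyses used to
    anchor and interpret chromosome-scale diploid oat (Avena) assemblies:
    assembly summary statistics (N50/L50, GC, >=20-N gap accounting),
    perfect-identity placement of tag-level haplotype markers, linkage-group
    assignment and collinearity-based chromosome-arm merging, deconvolution of
    hexaploid linkage groups into A/C/D subgenome origins with intergenomic
    translocation detection, majority-rule synteny orthology, Nei-Gojobori
    (1986) synonymous-divergence (Ks) estimation with molecular-clock
    calibration and dating, SNP filtering with sliding-window LD pruning and
    bootstrapped neighbor-joining phylogenies, and tandem-repeat discovery for
    centromere and telomere landscape profiling. A synthetic-data generator
    with ground-truth tables makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    methods,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
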