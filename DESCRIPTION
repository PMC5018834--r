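Package: h2aglyco
Title: Glycopeptide Mass Spectrometry, Isoform Phylogenetics and Peak
    Annotation for Histone H2A Ser40 O-GlcNAcylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the three computational arms of an H2A Ser40
    O-GlcNAcylation analysis: in-silico Lys-C digestion, monoisotopic
    mass arithmetic, HexNAc precursor pairing, HCD b/y/internal fragment
    enumeration, spectrum annotation and glycosite localization;
    cross-species classification of canonical H2A isoforms by the residue
    homologous to mouse position 40, with neighbor-joining trees and an
    isoform-type clustering score; and ChIP-seq peak annotation against
    gene models (TSS/gene body/intergenic, exon/intron fractions, target
    gene overlaps, expression association). Seeded synthetic-data
    generators emulate each input so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    jsonlite,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
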