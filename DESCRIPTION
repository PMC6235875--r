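Package: seedvar
Title: Cultivar-Group Differential DNA Polymorphism Discovery and
    Seed-Specific Candidate Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a genome-wide polymorphism-to-candidate-gene
    workflow for contrasting cultivar groups (two small-seeded versus two
    large-seeded chickpea cultivars): classification of SNP, MNP, InDel
    and complex variants, depth and alternate-fraction site filters, a
    10-bp clustering density filter, discovery of variants that
    differentiate the two cultivar groups, strand-aware region and coding
    consequence annotation (synonymous, non-synonymous, large-effect),
    transition/transversion and InDel-length spectra, 100-kb window
    densities, highly polymorphic gene outliers, a tissue-specificity
    index over 29 tissues for seed-specific gene screening, a fold
    change/q-value differential-expression gate, QTL interval
    containment, and candidate-gene intersection. Ships a deterministic
    synthetic-data generator that emits FASTA/GFF3/VCF/BED/TSV with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
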