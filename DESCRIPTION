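Package: pgmap
Title: Proteogenomic Peptide-to-Genome Mapping and Annotation Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A shotgun-proteogenomics analysis toolkit: maps MS/MS-identified
    peptides onto genomic coordinates by exact six-frame translation search,
    classifies each peptide's genomic context (known exonic, intronic,
    exon-donor-spanning, exon-acceptor-spanning, intergenic), updates GFF3
    genome annotation with peptide evidence features, and emits master-slave
    gene/peptide CSV reports, a relational table export, and gene-model
    visualizations in SVG and PNG. Includes a deterministic synthetic-data
    generator that produces genomes, annotations and peptide identification
    tables with known class labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
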