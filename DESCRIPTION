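Package: pgxtranslate
Title: Star-Allele Diplotype Translation for Pharmacogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Curates pharmacogene star-allele haplotype tables, encodes
    haplotypes numerically, infers per-gene diplotypes from unphased VCF
    genotype profiles by sum-vector matching, and classifies samples into
    wild-type/variant metabolizer status categories. Includes per-variant
    translation, gene and sample summary statistics, knowledge-base update
    operations (adding haplotypes, creating gene tables), pharmacogene
    landscape statistics over shared-drug gene graphs, and a synthetic
    fixture generator producing haplotype tables and multi-sample VCFs with
    known ground-truth diplotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
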