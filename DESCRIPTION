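Package: evcfkit
Title: Genotyping Clinically Informative Sites from gVCF Non-Variant Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves genotypes at clinically informative sites -- including
    homozygous-reference sites invisible to a standard VCF -- from the
    non-variant block records of a gVCF, and writes a compact extended VCF
    (eVCF) carrying the catalog provenance and clinical annotations in its
    header and INFO fields. Includes catalog ingestion (dbSNP-, ClinVar- and
    GWAS-catalog-style files), classification of reference-genome minor and
    risk alleles, genotype concordance evaluation against array callsets with
    strand normalization and a probe-interference filter, per-base coverage
    QC (gap detection, region coverage fractions, GC/AT window classes,
    binomial coverage thinning), and a deterministic synthetic-data generator
    with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
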