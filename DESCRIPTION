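Package: poleSig
Title: Stratification and Proofreading-Signature Context Analysis of POLE-Mutated Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting somatic POLE variants in tumor genomic
    profiles. Parses protein-level POLE variant calls, annotates them against
    a domain map of the POLE catalytic subunit and a curated catalog of 20
    exonuclease-domain (ExoD) proofreading driver alleles, and stratifies
    tumors into four groups by tumor mutational burden (TMB) and driver
    co-occurrence. Classifies coding substitutions into the 96 trinucleotide
    single-base-substitution (SBS) channels, builds POLE-proofreading
    signature context sets (SBS10a, SBS10b, SBS14, SBS28) by a >1%
    channel-inclusion rule, and computes the fraction of co-occurring POLE
    variants that fall in proofreading contexts. Includes rule-based
    classification of protein-stability effects (ddG cutoff) and neoantigen
    immunogenicity (dual 0.5 threshold), nonparametric group comparisons with
    FDR control, and a seeded synthetic-cohort generator so the whole
    pipeline runs and is testable without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'channels.R'
    'variants.R'
    'domains.R'
    'drivers.R'
    'stratify.R'
    'signatures.R'
    'stats.R'
    'annotations.R'
    'simulate.R'
    'io.R'
    'pipeline.R'
    'extdata.R'
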