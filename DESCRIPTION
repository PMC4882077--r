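Package: itsloci
Title: Intragenomic ITS Variation, In Silico CAPS Genotyping and Two-Locus
    Inheritance in Amphithallic Mushrooms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting intragenomic variation of the nuclear
    ribosomal internal transcribed spacer (ITS) in basidiomycetes with an
    amphithallic life cycle. Classifies cloned ITS amplicon sequences into
    haplotype types, variants and PCR chimeras; models superposed Sanger
    chromatograms including indel-induced masking of polymorphic peaks;
    performs in silico PCR-RFLP (CAPS) digestion with degenerate restriction
    sites, gel co-migration and band-visibility rules; classifies
    single-spore isolates as homokaryons or heterokaryons by a multilocus
    genotype test; infers two-locus ITS genotypes in the presence of a null
    allele; runs Mendelian segregation and linkage chi-square tests and
    evaluates competing inheritance hypotheses; and simulates random
    tetrasporic meiosis with post-meiotic mitosis to generate synthetic
    clone libraries and single-spore-isolate genotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
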