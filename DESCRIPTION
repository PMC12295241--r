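Package: ftindelscan
Title: Promoter Indel Genotyping and Flowering-Time Association for Lupin FT Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking promoter and intron insertion-deletion
    polymorphisms of FLOWERING LOCUS T (FT) homologs to flowering phenology
    in a diversity panel. Calls indels and SNP loci from gapped multiple
    sequence alignments against a reference, maps positions onto a
    transcription-start-site relative axis, models PCR marker assays over the
    variant catalogue (amplicon size prediction, presence/absence variants,
    gel resolvability, 0/1/2 genotype scoring, minor allele frequency
    screening), performs rank-based marker-trait association with Bonferroni
    correction, scans promoter sequences for transcription-factor binding
    sites (IUPAC consensus and frequency-matrix models) with a
    polymorphic-region exclusivity filter, and simulates complete synthetic
    diversity panels (alignments, genotypes, two-season phenology) for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
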