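Package: graftmobile
Title: Graft-Mobile mRNA Discovery from Allele-Specific RNA-Seq
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies long-distance mobile transcripts in plant heterografts
    from accession-diagnostic SNPs. Builds accession-specific reference SNP
    sets from hard-filtered variant records; separates genuine foreign-allele
    reads from sequencing error with a beta-binomial Bayes-factor gate that
    uses matched homograft counts; calls high-confidence mobile transcripts,
    classifies their phosphate-condition specificity, and computes mobile
    abundance and the mobile index. Also covers TRAP-seq based
    translated/untranslated partitioning with translational efficiency, a
    simplified differential-expression decision rule, RNA secondary-structure
    statistics (minimum free energy per nucleotide, GC content) with
    distribution comparisons, targeted DMS-MaPseq reactivity profiling, and
    in-silico CAPS/dCAPS genotyping. Seeded synthetic-data generators make the
    whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    DESeq2,
    pROC,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
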