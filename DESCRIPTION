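Package: scubr
Title: Synonymous Codon Usage Bias Analysis for Polyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts coding sequences from genome FASTA and GFF3 annotation
    under strict frame/start/stop/ambiguity filters, counts codons genome-wide,
    by subgenome, by exon count and by exon position (with the split-codon
    attribution rule for intron-interrupted codons), and computes synonymous
    codon usage bias statistics: per-amino-acid C/G:A/T ending ratios, third-base
    ending frequencies, RSCU, CAI and the effective number of codons. Includes
    DNA-methylation-context statistics (NXA/NXG second-position ratios and
    NT|X/NC|X codon-junction triplet ratios that trace CpG deamination),
    chi-square contingency tests with pairwise partitioning and compact letter
    displays, Welch t-tests, coefficients of variation, Pearson correlation,
    average-linkage clustering and principal component analysis of codon usage
    profiles, and a seeded synthetic-genome generator with known codon bias,
    interior-exon A/T tilt and CpG-deamination conversion rates so that every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
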