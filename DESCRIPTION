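Package: milkvar
Title: Milk Protein Gene Variants, Allele Typing and Casein Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of targeted DNA sequencing of the six bovine
    milk protein genes (CSN1S1, CSN2, CSN1S2, CSN3, LALBA, LGB). Loads
    transcript models with strand-aware genomic/CDS/protein coordinate
    arithmetic, normalizes and decomposes variants from VCF, applies a
    read-depth genotype filter, predicts coding consequences with
    signal-peptide-aware (mature-protein) residue numbering including
    frameshift/premature-stop arithmetic, assigns named milk protein alleles
    from a site catalog, estimates casein haplotype frequencies from unphased
    diploid genotypes by expectation-maximization, and scans UTR/flanking
    variants for gain and loss of microRNA seed-match sites and position
    weight matrix transcription factor binding sites. A deterministic
    synthetic-data generator emulates a multi-breed cohort genotyped at
    multi-exon genes so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
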