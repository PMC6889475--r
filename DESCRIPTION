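Package: ldregion
Title: Experiment-Specific Linkage Disequilibrium Regions and Annotations for Candidate SNPs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates pairwise linkage disequilibrium (r-squared) between
    biallelic SNPs from unphased diploid genotypes supplied as a VCF file or a
    folder of per-individual SNP-array exports, delineates the genomic region
    genetically linked to each candidate SNP at a user-chosen r-squared
    threshold, and extracts every annotated feature (gene, mRNA, CDS, ...)
    overlapping those regions from a GFF/GTF/GFF3 file. Includes two r-squared
    estimators (allele-dosage correlation and EM haplotype-frequency
    estimation), dataset-wide average linked distance and genome-coverage
    estimates, a checkpointing pipeline runner that allows re-analysis at
    higher thresholds without recomputing LD, and a seeded synthetic-fixture
    generator with controllable LD-block structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
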