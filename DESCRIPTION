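Package: pinesnp
Title: Candidate-Gene SNP Diversity, Linkage and Marker-Assisted Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for candidate-gene SNP studies in outcrossing
    tree populations: nucleotide diversity and neutrality statistics (pi,
    Watterson's theta, Tajima's D, Fu and Li's D*/F*, Fay and Wu's H,
    Hudson-Kaplan Rm) from haplotype alignments; Nei-Gojobori Ka/Ks;
    EM-based haplotype-frequency estimation and pairwise linkage
    disequilibrium (r2, D') from unphased diploid genotypes; haplotype-block
    partitioning with dominant-haplotype calling; per-locus Hardy-Weinberg
    tests; one-way ANOVA single-marker association with contribution R2;
    TagSNP selection; and genotype-combination marker-assisted selection
    with selection ratio, differential and realized genetic gain. Includes
    a coalescent-based synthetic-data generator producing study-shaped
    alignments, diploid genotype panels in Hardy-Weinberg proportions and
    quantitative traits with planted per-SNP effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
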