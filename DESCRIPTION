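Package: popgenscan
Title: Windowed Population-Genomic Scans, Introgression Statistics, and
    Coalescent Simulation for Fragmented Butterfly Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic inference from multi-sample SNP
    data: per-window nucleotide diversity, Tajima's D, Weir-Cockerham F_ST
    and absolute divergence d_xy; four-taxon ABBA-BABA introgression
    statistics (Patterson's D and f_d) with block-jackknife uncertainty and
    peak detection; derived-allele mutation-load analysis from polarized
    site-frequency spectra; effective-population-size estimation from
    diversity and isolation-by-distance regression on geodesic distances;
    mtDNA haplotype collapsing and minimum-spanning haplotype networks; and
    a structured-coalescent simulator (population splits, migration,
    bottlenecks, admixture pulses, neutral versus deleterious site classes)
    that generates genotype matrices, VCFs and truth logs for validating
    the whole inference chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    geosphere,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
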