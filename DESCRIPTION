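Package: sscoloc
Title: Simple Sum Colocalization of GWAS and Molecular QTL Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-based colocalization of a primary genome-wide association
    study (GWAS) signal with secondary SNP-level association datasets such as
    expression quantitative trait loci (eQTLs), using the two-stage Simple Sum
    test. Summary statistics are harmonized across datasets and a linkage
    disequilibrium (LD) reference (a PLINK-style square matrix file or
    genotypes in VCF), a Bonferroni-gated region-wide screen is followed by the
    GWAS-weighted Simple Sum statistic calibrated under an LD-implied null, and
    results across genes and tissues are assembled into a sentinel-coded
    heatmap matrix together with plot-ready regional summaries (LD colour bins,
    windowed minimum p-value traces, collapsed gene models). A synthetic-locus
    generator provides genotypes, LD and summary statistics under named
    colocalization scenarios for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
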