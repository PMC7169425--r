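Package: rohatlas
Title: Runs of Homozygosity, Genomic Inbreeding and Pooled-Heterozygosity
    Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide characterization of runs of homozygosity (ROH),
    genomic inbreeding (F_ROH), ROH islands and pooled-heterozygosity
    (Hp/ZHp) selective-sweep scanning for diploid biallelic SNP panels,
    with a family-based calibration of ROH-calling parameters against
    pedigree kinship and a gamete-dropping simulator that generates
    founder populations, pedigrees of known kinship class, recombination
    on a Mb-per-cM genetic map, genotyping noise and injected
    low/high-diversity regions with full ground truth. Defaults emulate
    reduced-representation SNP panels from a 22-chromosome, 567-Mb
    flatfish genome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
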