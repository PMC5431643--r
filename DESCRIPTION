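Package: ciliomap
Title: Homozygosity Mapping and Variant Triage for a Recessive Ovine Ciliopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping a lethal recessive hepatorenal fibrocystic
    (Meckel-like) trait in sheep flocks from SNP-chip genotypes, and for the
    downstream steps that take a mapped locus to a genotyping assay: detection
    of per-animal runs of homozygosity and cross-animal concordant
    homozygous-by-descent (IBD) regions with sliding-window error tolerance
    and carrier-fixation exclusion; segregation-based filtering of candidate
    variants with codon-level consequence annotation and a Grantham-distance
    plus ortholog-conservation deleteriousness proxy; in-silico PCR and
    restriction-digest (PCR-RFLP) genotype simulation; and the phenotype
    statistics used for morpholino rescue assays (exact two-tailed Fisher
    tests by hypergeometric enumeration) and primary-cilium morphometry.
    A synthetic-data module generates flock genotype panels with a planted
    ancestral haplotype, variant call sets, amplicon templates, embryo grade
    tables and cilium length samples with the statistical structure the
    analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
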