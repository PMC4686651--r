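Package: clonarch
Title: Clonal Architecture Inference for SF3B1-Mutant Myelodysplastic Syndromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of clonal architecture and clonal dynamics in
    myelodysplastic syndromes with ring sideroblasts from targeted amplicon
    and exome sequencing data. Implements a somatic-variant filter cascade
    (read-level quality filters, an exact Fisher somatic test against paired
    normals, whole-genome-amplification artifact filters, and xenograft
    concordance rules), mutant allele burden (MAB) quantification with
    replicate pooling and detection floors, single-colony genotype calling,
    perfect-phylogeny clone-tree reconstruction from colony genotype
    matrices, classification of clonal trajectories between paired samples,
    and loss-of-heterozygosity segmentation from germline SNP allele
    fractions. A seeded clone-mixture simulator generates allele-count
    tables with the statistical structure the analysis assumes, so every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
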