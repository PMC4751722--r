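Package: ploidyOrigin
Title: Detection and Mechanistic Classification of Spontaneous Polyploids
    from Microsatellite Genotypes and DNA Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect spontaneous polyploid individuals in a
    polyploid fish cross and to identify the mechanism of genome
    duplication (second-polar-body retention versus apomixis or
    premeiotic endomitosis versus polyspermy) from flow-cytometric or
    densitometric DNA-content measurements and presence-only multilocus
    microsatellite genotypes. Implements private-allele coding and the
    paired per-locus test battery, functional-ploidy calling against a
    per-genome-set reference, zygote ploidy and chromosome-number
    arithmetic for arbitrary gamete/fertilization models, an exclusion
    classifier for the duplication mechanism, and a seeded simulator of
    polysomic crosses (tetraploid dam by hexaploid sire by default) with
    known ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'genotype-io.R'
    'synthetic-cross.R'
    'ploidy.R'
    'private-alleles.R'
    'mechanism.R'
    'pipeline.R'
RoxygenNote: 7.3.3
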