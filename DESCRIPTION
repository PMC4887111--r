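Package: cypdose
Title: Allelic Dosage and Structural Flexibility Analysis of CYP1B1 Glaucoma Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to connect in vitro enzyme activities of CYP1B1 missense
    variants to glaucoma phenotypes. Implements dual-luciferase and
    luminogenic-substrate assay normalization with replicate statistics,
    cycloheximide-chase protein turnover analysis, an allelic dosage model
    that infers genotype-level retinol and 17beta-estradiol metabolizing
    activities from per-allele measurements, a rule-based classifier of
    genotype-to-phenotype concordance for primary congenital and open-angle
    glaucoma, and an anisotropic elastic-network normal mode screen of
    per-residue flexibility (mode 7-9 RMSF, log2 mutant/wild-type ratios,
    segment summaries, ensemble PCA). Ships the curated variant catalog as
    a plain-text fixture together with simulators for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, GenomicVariation, StructuralPrediction, Classification
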