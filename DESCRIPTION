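Package: glypheno
Title: Genotype-Phenotype Scoring for Glycine Decarboxylase Missense Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative genotype-phenotype tools for non-ketotic hyperglycinemia
    (NKH) caused by missense mutations in glycine decarboxylase (GLDC). Implements
    a four-domain clinical outcomes score (COS) with cohort eligibility filtering,
    an 18-parameter multiparametric mutation score (MMS) for homozygous genotypes
    extended by four non-missense allele parameters for compound heterozygotes,
    least-squares training of parameter weights against clinical outcomes (WMMS),
    cohort statistics (hypergeometric region enrichment, phi correlation of binary
    parameters, severity-separation t-tests, concordance counts), rescoring of
    two-chain protein-protein docking decoys by interface conservation and
    ligand-site distance, and seeded synthetic-data generators so every stage is
    testable without external downloads. Ships the published cohort and weight
    tables as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
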