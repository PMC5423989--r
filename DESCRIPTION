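Package: df4nano
Title: Tiered Grouping of Nanomaterials by the DF4nanoGrouping Decision Framework
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An auditable implementation of the ECETOC three-tier decision-making
    framework for the grouping and testing of nanomaterials (DF4nanoGrouping),
    which assigns nanomaterials to four hazard-relevant main groups: soluble
    (MG1), biopersistent high-aspect-ratio (MG2), passive (MG3) and active (MG4)
    nanomaterials. Tier 1 evaluates intrinsic properties (water solubility,
    particle morphology, composition), Tier 2 system-dependent properties and in
    vitro effects (dissolution in biological fluids, surface reactivity,
    dispersibility, lung epithelial cytotoxicity, the NR8383 alveolar-macrophage
    assay), and Tier 3 confirms or corrects the non-animal assignment with rat
    short-term inhalation study results (NOAEC range banding, biopersistence,
    biodistribution subgrouping). Every threshold comparison is recorded in an
    ordered audit trace, missing data are handled precautionarily, and a
    25-material case-study dataset plus a seeded synthetic-material generator
    support regression and property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
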