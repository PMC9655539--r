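Package: mtscreen
Title: Multi-Target Virtual Screening Hit Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable triage cascade for multi-target virtual screening
    campaigns against panels of protein targets. Takes per-compound,
    per-target docking scores and predicted affinity ranges, derives
    selection thresholds from reference-ligand re-docking profiles, applies
    triple-activity score gates, PAINS and Schiff-base substructure alerts,
    per-target and product affinity constraints with rank fusion by the Ki
    multiplication product, consensus pharmacophore filtering of docked
    poses, and blood-brain-barrier/toxicity gating, and reports compound
    attrition per stage. Includes a synthetic-library generator with
    planted triple-actives for end-to-end validation without commercial
    docking engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
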