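Package: acylomics
Title: Acyl-PTM Site Quantification, Coexpression Screening, and Companion Assay Analytics
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying lysine acylation of metabolic
    enzymes and its regulation by sirtuin deacylases. Implements a hepatic
    gene-coexpression screen with a resampling-based null distribution and
    hypergeometric gene-set over-representation; label-free acyl-site
    quantification with protein-level normalization, low-abundance
    imputation, and per-site differential statistics; two-state van't Hoff
    thermal-unfolding fits for melting-temperature estimation; deterministic
    arithmetic for dye-reduction enzyme assays, radiolabel oxidation assays,
    and delta-delta-Ct qPCR; and volcano-style differential statistics for
    metabolite tables. A synthetic-data module generates every input with
    known ground truth so each stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
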