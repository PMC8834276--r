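Package: etcc
Title: Ecotourism Carrying Capacity and Delphi Impact Prioritization for
    Protected Areas
Version: 0.1.0
Authors@R:
    person("ETCC", "Maintainers", email = "etcc@example.org", role = c("aut", "cre"))
Description: Tools for estimating the tourism carrying capacity of protected
    areas with the Cifuentes framework: physical carrying capacity (PCC) from
    zone area, per-visitor space standards and a rotation factor; real
    carrying capacity (RCC) from climatic limiting (correction) factors; and
    effective carrying capacity (ECC) from the management-capacity deficit of
    the ranger workforce. Includes multi-round Delphi aggregation of Likert
    questionnaires (per-item statistics, within-dimension competition ranking,
    dimension means, item removal and expert attrition), seeded synthetic
    generators for site datasets and expert panels, delimited-text readers and
    writers with validation, a worked dataset for three Iranian protected
    areas, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
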