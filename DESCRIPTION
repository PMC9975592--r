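Package: pakchoiN
Title: Photothermal Growth, Critical Nitrogen Dilution and Nitrogen
    Demand Modelling for Pakchoi
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing and budgeting nitrogen in greenhouse
    pakchoi (Brassica campestris ssp. chinensis). Accumulates a cumulative
    photothermal effect (LTF) from hourly temperature and photosynthetically
    active radiation, fits LTF-driven exponential growth and nitrogen-uptake
    models, evaluates the critical nitrogen dilution curve with
    maximum/critical/minimum envelopes, computes the nitrogen nutrition
    index (NNI) and classifies crop nitrogen status, and converts the gap
    between critical and actual nitrogen into per-plant demand and supply
    recommendations given a nitrogen use efficiency. Includes a synthetic
    greenhouse-trial generator and a parameter-recovery harness so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
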