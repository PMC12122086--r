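Package: eshpflow
Title: Personalized Coronary Blood Flow and Metabolic Monitoring for Ex Situ Heart Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decision-support calculations for normothermic and subnormothermic
    ex situ heart perfusion (ESHP). Computes a personalized coronary blood flow
    (CBF) recommendation that balances myocardial oxygen delivery against the
    expected consumption of an individual donor heart, from donor sex and body
    weight (or a measured heart weight) and perfusate blood-gas values, with
    min-max normalization onto the clinically validated 500-800 ml/min window.
    Maintains a perfusion-session time series of arterial and venous blood-gas
    samples, derives oxygen-handling metrics (CaO2, CvO2, MVO2, MDO2, MEO2,
    delta-PO2, CVR), classifies lactate trends, issues electrolyte advisories,
    recalibrates the flow recommendation from measured oxygen consumption, and
    simulates synthetic perfusion runs with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
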