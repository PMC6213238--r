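Package: soildeg
Title: Biodegradation Kinetics of Organic Soil Conditioners
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: First-order biodegradation kinetics for organic soil conditioners
    (peat, strongly swelling polymer hydrogels) in soils and layered soil
    constructions. Converts closed-vial CO2 incubation measurements into
    basal respiration rates and decay constants, fits hydrothermal response
    surfaces (Q10 temperature factor, extremum moisture factor), simulates
    decay under seasonal or diurnal temperature forcing, fits exponential
    depth-attenuation profiles of biological activity and generates burial
    depth nomographs for soil construction design, and fits van Genuchten
    water-retention curves to track conditioner performance. Includes seeded
    synthetic-data generators with known ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
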