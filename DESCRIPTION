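Package: offtake
Title: Harvest Sustainability Assessment for Birds from Minimal Demography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rapid assessment of the sustainability of bird offtake when only
    limited demographic information is available. Estimates the intrinsic
    growth rate from adult survival (directly, or allometrically from body
    mass) and age at first breeding via the demographic-invariant method,
    computes allowable take under the potential biological removal (PBR),
    potential excess growth (PEG) and potential take level (PTL) rules on a
    theta-logistic population model, propagates parameter uncertainty by
    Monte Carlo into a distribution of the sustainable harvest index (SHI),
    and ranks candidate harvest levels by first- and second-order stochastic
    dominance for risk-averse decision support. Includes deterministic
    theta-logistic projection and yield-curve tools, YAML/JSON scenario
    files, batch CSV runs and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
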