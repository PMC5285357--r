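Package: shootallom
Title: Allometric Models of Leaf Area and Internode Length for Apple Shoot
    Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts individual and total leaf area of the three apple shoot
    types (bourse shoot, rosette, vegetative shoot) and the position of leaves
    along the spur from two easily scored inputs per shoot: leaf number and the
    length of the biggest leaf. Leaf size along a shoot follows a Lorentz
    profile over normalized rank whose scale parameter is obtained by inverting
    an arctan closed form of the profile integral; blades are treated as
    ellipses with a genotype-specific width/length ratio; cumulative internode
    length follows a logistic model over the bourse to bourse-shoot continuum;
    shoot maturity is decided by growing-degree-day accumulation. The package
    includes the full parameterization, calibration and testing workflow and a
    synthetic orchard-data generator with recorded ground truth so every stage
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
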