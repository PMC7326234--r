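Package: paleoenz
Title: Comparative Analysis of Ancestral and Modern Enzyme Homologs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative comparison of resurrected ancestral enzymes with
    their modern homologs. Provides catalytic-promiscuity indices from
    Michaelis-Menten kinetics, two-state urea-unfolding thermodynamics by
    the linear extrapolation method, apparent melting-temperature fits,
    crystallographic B-factor Z-score normalization and differencing,
    sequence/structure substitution censuses with solvent exposure,
    channel clearance-radius profiles with conical-frustum volumetrics
    and pinch-point detection, and a synthetic-data module that generates
    every input type with analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
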