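Package: crossmodal
Title: Consistency and Isomorphic Structure in Cross-Modal Association Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for trial-level cross-modal association
    experiments in which participants repeatedly choose colors for auditory
    or visual items (e.g., vowel sounds). Provides deterministic sRGB to
    CIELuv/CIELab conversion under illuminant D65, CIEDE2000 perceptual
    color differences, temporal consistency scoring with a synesthete
    classification cutoff, nearest-phoneme (Voronoi) categorization of
    vowel stimuli in F1-F2 formant space, and a Mantel-permutation
    "structure" score quantifying how isomorphically a participant maps
    stimulus space onto color space. Includes a synthetic-cohort simulator
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    farver,
    vegan,
    class,
    optparse,
    withr,
    grDevices
Config/testthat/edition: 3
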