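Package: chemmorph
Title: Headless 2D Chemical Structure Drawing, MOL V2000 Interchange and
    Morphing Animation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless library for 2D chemical structure depiction and
    morphing-based visualisation of molecular vibrations and reaction
    sequences. Provides a chemical-drawing data model (atoms, bonds,
    annotations, atomic shells, backgrounds), MDL MOL V2000 import and export
    with a leftmost-coupling-atom attachment rule, affine (three-point) and
    projective (four-point, unit-squares method) region mappings, a stepwise
    shape-and-colour morphing engine with automatic atom/bond correspondence
    and triatomic vibration presets, and deterministic SVG, raster and
    animated-GIF rendering, together with a small command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
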