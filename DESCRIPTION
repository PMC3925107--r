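Package: habtile
Title: Design and Export of Informationally Complex Habitat Tiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing artificial-substrate tiles with controlled
    informational (Shannon-entropy) habitat complexity. Five complexity
    variables -- number of object types, their relative abundances, object
    density, discrete size variability, and spatial arrangement -- are
    realised on a tile either by buffered random sequential adsorption or by
    a deterministic ordered grid. Designs can be edited per object under
    constraint revalidation and exported as spreadsheet CSV, CAD-ready DXF
    (R12 ASCII), and SVG drawings for fabrication of experimental substrates
    in complexity-biodiversity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
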