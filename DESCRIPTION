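Package: cleavekit
Title: Knockout Peptidomics Analysis of Prohormone-Processing Proteases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the substrate specificity of gut prohormone-processing
    proteases from knockout-versus-wildtype label-free peptidomics. Provides
    precursor/feature registries with amidation logic, total-intensity
    normalization, replicate-completeness filtering, down-shifted normal
    imputation, pooled-variance Student's t statistics with permutation-based
    q-values, z-scaled clustered abundance profiles, cleavage-window sequence
    logos, X-P/A dipeptide-pair detection, targeted MS1 isotope-envelope
    verification via the isotope dot product, and a ground-truthed in-silico
    prohormone-processing simulator covering dibasic endoproteolysis,
    carboxypeptidase trimming, C-terminal amidation and DPP4-style
    aminopeptidase activity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
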