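Package: dnmap
Title: Deep Neural Maps for Topology-Preserving Stratification of miRNA
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised stratification of miRNA expression cohorts with a
    Deep Neural Map: a symmetric autoencoder with geometric-series layer
    widths is pre-trained on total-count-normalized expression profiles, a
    self-organizing map is pre-trained on the latent embedding, and the two
    are jointly fine-tuned under a combined reconstruction plus winning-node
    distance loss. Includes quality control and stratified splitting for
    count matrices, majority-vote node labelling with accuracy, sensitivity
    and specificity evaluation, multi-class node discovery, an activation
    gradient method that attributes latent activity to individual miRNAs,
    and a negative-binomial synthetic cohort generator with planted markers
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
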