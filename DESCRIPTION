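Package: flfsi
Title: Feature-Level Fusion and Selection for Paired Ultrasound Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tri-channel (RGB) two-dimensional principal component analysis
    for stacks of same-size colour images, with binary particle swarm
    optimisation (a classic sigmoid-transfer variant and an improved
    sign-quantised variant) selecting the projected feature vectors used for
    image reconstruction under a sparsity-penalised reconstruction-error
    fitness. Includes swarm-consensus plus l2-energy component selection,
    feature-level fusion of two ultrasound modalities (conventional
    sonography and contrast-enhanced ultrasound) at a tunable mixing ratio,
    a seeded generator of paired synthetic ultrasound-like images with
    ground-truth region masks, a reproducible end-to-end pipeline with
    manifests, and a YOLO-segmentation dataset export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
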