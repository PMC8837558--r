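Package: sarcopop
Title: Virtual Populations of a Sarcomere Contraction Model via Adversarial Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constructs virtual populations of a phenomenological mean-field model
    of cardiac sarcomere contraction from unloaded-shortening recordings of isolated
    myocytes under a two-group (control versus inotrope) design. Provides the
    mechanistic model (calcium transient, thin-filament activation, cross-bridge
    group dynamics, passive tension) with unloaded, isometric and isosarcometric
    force-calcium protocols; twitch feature extraction by nonlinear least squares;
    a feed-forward neural-network surrogate of the parameter-to-feature map; a
    factorized generative adversarial network that infers per-group parameter
    distributions under the constraint that drug-insensitive parameters share one
    distribution across groups; permutation-based (mean decrease accuracy) global
    sensitivity analysis; and a synthetic-data generator emulating the experimental
    design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    MASS,
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
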