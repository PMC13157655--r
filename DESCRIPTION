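Package: choicernn
Title: Biologically Constrained Recurrent Networks for Economic Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains excitatory-inhibitory recurrent neural networks with
    Dale's law on a family of economic choice tasks using proximal policy
    optimization (actor-critic reinforcement learning), and provides the
    accompanying analysis suite: logistic choice models with relative
    value, risk attitude and choice consistency; single-neuron selectivity
    regressions and temporal stability; population dimensionality
    (participation ratio), principal-component regression, subspace angles
    and Procrustes alignment; connectivity analyses, computational
    lesions and circuit-motif extraction; and a toy feedforward model of
    multiplicative value computation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
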