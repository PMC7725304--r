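Package: triggerhair
Title: Ion-Flux and Turgor Dynamics, KDM1 Channel Gating, and Tissue
    Specificity for the Venus Flytrap Trigger Hair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of potassium/anion fluxes and turgor
    pressure during action potentials in the mechanosensory cells of the
    Venus flytrap (Dionaea muscipula) trigger hair, using an explicit-Euler
    two-compartment model with a turgor threshold for action-potential
    initiation. Implements the Boltzmann open-probability model of the
    hyperpolarization- and acid-activated K+ channel KDM1 together with
    the pH-dependent half-activation voltage model and least-squares
    fitting of activation curves, current normalization, Nernst-slope and
    fractional-block statistics. Scores gene tissue specificity by Shannon
    entropy Q-values with a Laplace-tail threshold and intersects them
    with differential-expression filters to call bona fide tissue-specific
    genes. Includes seeded generators for negative-binomial expression
    matrices with planted tissue-specific genes, matching differential
    expression tables, and noisy activation/current-voltage datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    limma,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
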