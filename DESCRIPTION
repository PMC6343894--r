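Package: hydrollp
Title: Hydrodynamics and Fish Behaviour Under Simulated Hydropeaking with
    an Artificial Lateral Line Probe
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing indoor-flume hydropeaking experiments in
    which the local flow field is characterised with a fish-inspired
    artificial lateral line probe (LLP) and fish responses are scored as
    physiological endpoints and behaviour-metric frequencies. Provides
    pressure-derived flow variables (mean front pressure, mean front
    fluctuations, mean pressure asymmetry) computed from six-channel
    differential pressure traces, grid-based spatial summaries of the
    structure wake and open flume areas, an ethogram frequency coder, and
    hand-implemented nonparametric inference (Kruskal-Wallis with tie
    correction, Nemenyi pairwise contrasts, correspondence analysis, and
    two-way distance-based permutational multivariate ANOVA). A synthetic
    data module generates pressure traces, overdispersed behaviour counts
    and physiology samples with the statistical structure the analysis
    assumes, so the full pipeline is exercisable end-to-end without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
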