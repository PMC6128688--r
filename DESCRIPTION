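Package: mechanopatch
Title: Simulation and Analysis of Mechanosensitive Channel Patch-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of mechanosensitive (Piezo-type)
    channel recordings from whole-cell poking assays and pressure-clamped
    membrane patches, together with a stochastic Markov gating simulator that
    generates sweeps with known ground truth. Implements whole-cell
    inactivation metrics (baseline, peak, 75-ms slow current, slow fraction,
    fast component, exponential inactivation fits), single-channel
    amplitude-histogram analysis (Gaussian-mixture level detection, unitary
    current spacing, conductance regression across voltages, ensemble
    averaging, idealization), ion-selectivity biophysics (Nernst and
    Goldman-Hodgkin-Katz potentials, bi-ionic permeability ratios including
    the Fatt-Ginsborg divalent relation, Henderson liquid-junction potentials
    from a bundled ionic mobility table), and cohort proliferation statistics
    (growth normalization, exponential growth-constant fits, Welch one-tailed
    t-tests). Sweeps travel in a documented JSON container with a delimited
    text fallback, and a command-line dispatcher ties the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    mclust,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'cli.R'
    'cohort-stats.R'
    'filters.R'
    'gating-model.R'
    'gating-sim.R'
    'mechanopatch-package.R'
    'selectivity.R'
    'single-channel.R'
    'wholecell.R'
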