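Package: hrmcompete
Title: Competitive Fitness Estimation from High-Resolution Melting Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating allele proportions in mixed spore samples
    from post-PCR high-resolution melting (HRM) curves, and for estimating
    relative competitive fitness of microbial genotypes from serial-transfer
    competition experiments. Melt curves are normalized, melting temperatures
    are called from the spline-interpolated negative first derivative, and a
    per-plate normalized-RFU difference signal at a discriminating temperature
    feeds a Bayesian linear standard curve that is inverted to give a full
    posterior for the marked-allele proportion of each unknown sample.
    Relative fitness (the per-transfer selection on the log-odds scale) is
    then estimated with hierarchical Bayesian logistic-slope models that
    propagate the per-sample proportion uncertainty through a
    measurement-error layer. Includes a synthetic-data generator for melt
    plates and competition trajectories with known ground truth, HPDI and
    split R-hat diagnostics, and a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    rjags,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    coda,
    yaml,
    optparse
SystemRequirements: JAGS (>= 4.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
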