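Package: latentnav
Title: Neural Encoding, Decoding and Network Models for Latent-State Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how neural populations track continuously
    varying latent task states during closed-loop navigation by optic flow.
    Provides a synthetic closed-loop navigation simulator with task
    manipulations (optic-flow density, joystick gain, trajectory
    perturbations), a generative coupled Poisson spiking model, behavioral
    ROC/AUC psychometrics, a coupled Poisson generalized additive encoding
    model with MAP estimation and grouped backward elimination, time-rescaled
    population sequence statistics, linear population decoding with
    error-propagation analyses, stability and mixed-selectivity statistics,
    task-relevant dimensionality by canonical correlation analysis, and a
    closed-loop recurrent network model trained by backpropagation through
    time.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
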