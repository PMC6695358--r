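Package: ocupharm
Title: Active-Inference Simulation of Oculomotor Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a delayed (memory-guided) saccade task as a hybrid
    generative model: a discrete Markov-decision-process agent that plans
    saccades by minimising expected free energy, coupled to a continuous
    second-order attractor model of the oculomotor plant. Four precision
    parameters act as synthetic neuromodulators - likelihood precision
    (acetylcholine), transition precision (noradrenaline), policy precision
    (dopamine) and a motor fixation-prior precision (GABAergic collicular
    gain) - and parameter sweeps reproduce drug-like changes in saccadic
    peak velocity, accuracy, timing, simulated dopaminergic precision
    updates and delay-period belief rasters. Includes dose-response sweep
    experiments, a precision-interaction experiment, synthetic parameter
    recovery by grid-search maximum likelihood, tidy accessors and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
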