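Package: noisynav
Title: Noise Robustness of Successor- and Predecessor-Feature Learning in
    Grid Worlds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation pipeline for comparing the noise robustness of four
    temporal-difference learning agents -- Q learning, Q(lambda) learning,
    successor-feature (SF) learning, and predecessor-feature (PF) learning
    with eligibility traces -- navigating deterministic grid worlds under
    Gaussian observation noise.  Provides the noisy grid-world environments
    (a 20-state chain and a 7x7 grid with a 5x5 navigable interior), the
    agents' linear update rules over noisy one-hot observations, a
    reproducible trial/experiment runner with a fast compiled inner loop,
    and the Monte-Carlo evaluation statistics (cumulative reward, episode
    lengths, moving averages, quartiles, SEM, threshold-based convergence)
    used to summarise the experiments, together with the analytic discounted
    occupancy oracle for validating successor-feature learning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    dplyr,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
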