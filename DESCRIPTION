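Package: gensmr
Title: Generalized Spatial Mark-Resight Models for Animal Density Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian generalized spatial mark-resight (genSMR) models for
    estimating the population density of animals that lack natural marks,
    combining a live-trap marking process, camera-trap resighting of marked
    and unmarked individuals, and GPS telemetry from marked animals. Latent
    identities of unmarked detections are resolved by Markov chain Monte
    Carlo with data augmentation, optionally constrained by observed sex as
    a partially identifying categorical covariate, and with an optional
    one-time activity-center relocation (transiency) between the marking
    and resighting periods. Includes conventional SMR and null spatial
    capture-recapture fits, a synthetic-data generator, a clustered
    camera-trap design simulation harness, posterior-mode and highest
    posterior density summaries, and readers and writers for tabular field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
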