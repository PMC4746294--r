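Package: flightlearn
Title: Simulation and Analysis of Flight-Simulator Skill-Learning Studies
    with EEG and fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing a four-group, four-day
    flight-simulator training study with concurrent neuroimaging. Includes a
    synthetic-data generator (flight telemetry, adaptive n-back logs,
    multichannel EEG, dual-wavelength fNIRS optical densities) with known
    ground truth; bespoke landing-performance metrics (impact g-force, flight
    path deviation, vertical-speed deviation and variance, control-input
    counts, missed-landing classification); information-scaled adaptive
    n-back scoring; online/offline/meta learning-rate decomposition;
    variance-homogeneity inference (two-sample F and Bartlett tests) with
    trial-wise outlier rejection; EEG theta/alpha band-power estimation with
    cluster-based permutation statistics over channel neighbourhoods; and
    modified Beer-Lambert law conversion of fNIRS optical densities with
    least-squares FIR filtering, canonical-HRF GLM betas, and
    Bonferroni-corrected day contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    geosphere
Config/testthat/edition: 3
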