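Package: earmotion
Title: Active Binaural Listening with Moving Ears
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates direction detection of an echo source by a binaural
    listener whose directional ears undergo periodic rigid rotations, as in
    CF-FM bats that move their pinnae while listening to the constant
    frequency part of an echo.  The forward model maps a target direction to
    an interaural level difference (ILD) time signal through a four
    microphone beamforming ear under roll-pitch-yaw motion histories.  The
    package scores whether that map is invertible with a degree of injection
    index, learns the inverse map with a small feed-forward neural network
    trained on simulated ILD signals, classifies ear motion patterns by the
    affine dimensions of their orbits in roll-pitch-yaw space, and runs the
    exhaustive motion-pattern sweeps that identify which motions permit
    accurate and robust direction detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
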