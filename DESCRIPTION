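Package: ejectr
Title: Analysis of Single-Molecule DNA Ejection Trajectories from Viral Capsids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing force-clamp optical-tweezers measurements of
    DNA exit from bacteriophage capsids. Converts extension/force traces to
    DNA contour length via the extensible worm-like-chain model, estimates
    sliding-window exit velocities and binned velocity-versus-filling
    profiles with bootstrap errors, detects pauses by Kalafut-Visscher
    BIC change-point segmentation qualified against static-tether control
    noise, characterises pause statistics (exponential inter-pause spacings,
    Clauset-Shalizi-Newman power-law tails of pause durations), and fits the
    Prandtl-Tomlinson thermally activated friction model to paired
    low/high-force velocity profiles to infer the friction periodicity d and
    mobility mu. Includes a calibrated stochastic trace generator emulating
    the reported statistical structure of phi29 DNA ejection so the whole
    pipeline is testable without experimental data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
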