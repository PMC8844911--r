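Package: fpmod
Title: Mediolateral Foot-Placement Modulation Analysis for Treadmill Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify step-by-step modulation of mediolateral foot
    placement during treadmill walking. Detects gait events from heel
    marker velocities, computes per-step spatial metrics (step width, step
    length, foot placement) and pelvis state over normalized step time,
    and estimates the partial correlation between step width and pelvis
    displacement controlling for pelvis velocity (rho_disp). Includes a
    model of an assistive/perturbing mediolateral force-field controller,
    a synthetic gait generator with known pelvis-to-step-width coupling
    for closed-loop validation, and paired nonparametric comparisons of
    direct effects and after-effects across protocol periods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
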