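Package: menisim
Title: Simulation of Traditional and 3D-Printing-Enabled Meniscus
    Transplantation Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Monte-Carlo micro-simulation comparing two care pathways for
    meniscus-deficient patients over a 20-year horizon: traditional
    allograft transplantation, where patients join a first-come
    first-served donor queue and are forced into total knee arthroplasty
    (TKA) after a two-year wait, and a 3D-printing-enabled pathway where a
    patient-matched implant is available immediately.  Post-transplant
    health is an annual-cycle Markov chain over the states no-issue,
    repair, reoperation and TKA, with a cap on repeat entries into the
    intermediate states.  The package provides the transition-matrix
    scaling rules used for implant-quality sensitivity scenarios, an exact
    analytic oracle for TKA absorption probabilities, per-patient cost
    accounting (waiting, transplantation, post-transplant treatment), and
    replication-averaged yearly summaries with broom-style tidiers and
    ggplot2 plotting.
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
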