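Package: rpmap
Title: Hybrid Resistive-Pulse and Optical-Imaging Analysis of Microfluidic Translocations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing simultaneous resistive-pulse (ionic current)
    and high-speed imaging recordings of microparticles translocating through
    microfluidic channels. Implements closed-form Coulter-counter amplitude
    models for straight and cavity-bearing channels (on-axis, off-axis and
    local-resistance forms), a physics-based simulator producing mutually
    consistent current traces and frame sequences with independent clocks,
    event detection in both data streams, coarse plus per-event fine clock
    alignment, and positional analytics: channel resistance maps, axial and
    lateral amplitude profiles, transit-time statistics and wide/narrow
    amplitude-ratio distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
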