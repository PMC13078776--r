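Package: lanetaxis
Title: Bacterial Chemotaxis in Confined Microfluidic Lanes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying Escherichia coli chemotaxis inside narrow
    microfluidic lanes, where chiral circular surface swimming and sidewall
    alignment make chemotactic drift depend on lane width. Implements a
    coarse-grained receptor/methylation signaling model mapped to motor
    clockwise bias and run-to-tumble switching, a vectorized agent-based
    run-and-tumble simulator with circular surface swimming, wall alignment
    and detention, and x-boundary recycling, the trajectory statistics used
    on particle-tracking exports (lag-regression drift velocity, mean-squared
    orientational displacement and rotational exponent, algebraic circle
    fits, velocity-drop tumble detection, sidewall/middle-region
    classification, truncated-exponential tumble-angle fits), a closed-form
    first-collision geometry for the optimal width-to-radius ratio with a
    Monte-Carlo cross-check, synthetic trajectory generators with known
    ground truth, and width/radius sweep drivers.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
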