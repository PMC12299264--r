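Package: harlrp
Title: Interpretable Dynamic Neural Networks for Wearable-Sensor Activity
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how dynamic neural networks classify human
    activity from six-channel wearable inertial data and where their
    decisions come from. Simulates labeled accelerometer/gyroscope windows
    with controllable per-class periodic structure, implements the full
    preprocessing chain (zero-row exclusion, class balancing, stratified
    splitting, per-class z-scoring), trains finite-impulse-response,
    LSTM and GRU sequence classifiers from scratch with
    backpropagation-through-time, accounts for their computational
    complexity in closed form, and explains predictions with epsilon-rule
    layer-wise relevance propagation at both the input-channel and
    hidden-unit level, including zero-crossing-rate quadrant analytics and
    class-conditional relevance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
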