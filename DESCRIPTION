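Package: emgfuse
Title: Parallel Pattern Recognition for Simultaneous Multi-Joint Myoelectric Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Decodes simultaneous elbow, wrist and hand motion intent from
    multi-channel surface electromyography (sEMG). Implements sliding-window
    segmentation, five time-domain features (enhanced mean absolute value,
    enhanced waveform length, slope sign change, root mean square, variance),
    from-scratch L2-regularized logistic regression trained by Polack-Ribiere
    conjugate gradients, closed-form one-vs-all linear discriminant analysis,
    and a parallel three-classifier fusion scheme that maps per-joint outputs
    onto 27 discrete and combined motion classes. Includes offline evaluation
    (macro F1, misclassification error, normalized confusion matrices,
    per-class 70/30 splits), real-time stream simulation (motion selection
    time, motion completion time, motion completion rate), rank-based
    comparison statistics (Mann-Whitney U with eta-squared effect size), and
    a synthetic sEMG generator emulating a 27-class acquisition protocol.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
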