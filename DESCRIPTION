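Package: vterisk
Title: Automated Padua Risk Assessment for Venous Thromboembolism from
    Electronic Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A dual-branch pipeline that automates the 11-item Padua risk
    score for venous thromboembolism (VTE) from electronic medical record
    (EMR) text.  Branch A is a disease-category classifier over diagnosis
    and symptom text: a deterministic hashing embedder feeds two stacked
    bidirectional recurrent encoders whose outputs are fused with a TF-IWF
    symptom weight vector and classified with a focal-loss softmax head.
    Branch B extracts clinical factors by lexicon-intervened segmentation
    with negation filtering, temporal anchoring for the recent-surgery
    window, and numeric rules for age, body-mass index and thrombophilia
    labs.  Includes multi-label ranking metrics (AUC, F1, Hamming
    distance, one-error, ranking loss, coverage), a seeded synthetic-EMR
    generator with planted gold labels, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
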