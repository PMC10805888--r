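Package: polypeval
Title: Evaluation Toolkit for Polyp Detection and Segmentation
    Generalisability Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metrics and leaderboard machinery for multi-centre colonoscopy
    polyp benchmarks. Implements COCO-style interpolated average precision
    with size-stratified variants for bounding-box detection, per-frame
    pixel-overlap metrics (Dice, Jaccard, precision, recall, accuracy, F2)
    and the average Hausdorff distance with per-test-set normalisation for
    binary-mask segmentation, a tolerance-gated deviation score that
    quantifies the generalisation gap between a seen reference test split
    and unseen-centre or unseen-modality splits, direction-aware rank
    aggregation with time banding and elimination rules, and a
    Friedman-Nemenyi per-frame comparison of methods. A seeded generator of
    challenge-shaped synthetic fixtures (manifests, binary masks, bounding
    boxes and perturbed predictions) makes the whole pipeline testable
    without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
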