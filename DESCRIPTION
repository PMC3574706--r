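Package: ecgsonfin
Title: Two-Lead ECG Heartbeat Detection and Neuro-Fuzzy Arrhythmia
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automatic two-lead (Lead II and V1) electrocardiogram
    analysis pipeline for portable-monitor settings. QRS complexes are
    marked sample-by-sample with a radial-basis support vector machine
    operating on the filtered Lead II signal and its first difference,
    cleaned by merge/delete post-processing, and segmented into
    200-dimensional two-lead beat feature vectors. Beats are classified
    into normal sinus rhythm, premature ventricular contraction, and
    left/right bundle branch block by a self-constructing neural fuzzy
    inference network (SoNFIN), a Takagi-Sugeno-Kang fuzzy model with
    online rule generation, recursive least-squares consequent training
    and gradient-descent antecedent tuning; an output-magnitude threshold
    rejects false markers and an RR-prematurity rule flags atrial
    premature beats. Includes an annotated synthetic ECG generator and
    beat-by-beat evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
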