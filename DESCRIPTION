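Package: afentropy
Title: Entropy-Based Atrial Fibrillation Detection from RR-Interval Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects atrial fibrillation (AF) from short RR-interval
    time series using a ranged-distance fuzzy entropy with a flexible
    tolerance threshold and a weighted heart-rate adjustment, alongside
    three established comparator measures: sample entropy (SampEn),
    fuzzy measure entropy (FuzzyMEn) and the coefficient of sample
    entropy (COSEn). Includes beat-level preprocessing (RR filtering,
    non-overlapping windowing, rhythm labelling, a 2-of-5 signal-quality
    noise gate), a full ROC evaluation protocol (grid thresholds, AUC,
    Youden and high-sensitivity and high-specificity operating points,
    paired DeLong AUC comparison) and a synthetic RR generator for AF-like
    and sinus-rhythm-like series so the whole pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
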