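Package: stvrepol
Title: Beat-to-Beat Short-Term Variability of Cardiac Repolarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimators of beat-to-beat short-term variability (STV) of
    cardiac repolarization from surface electrocardiograms and unipolar
    intracardiac electrograms. Implements an automatic activation-recovery
    interval (ARI) measurement based on a dynamic per-beat analysis window,
    QRS blanking, and the 60%-area point of the squared first derivative of
    the T-wave, and a fiducial-segment-averaging (FSA) QT measurement that
    aligns beats by leave-one-out cross-correlation at the R peak, QRS onset,
    and T-wave end. Provides the STV statistic with ectopy and pacing
    exclusion rules, Bazett rate correction, ST-deviation measurement,
    electrogram channel selection, Bland-Altman and Spearman agreement
    analysis, and a synthetic ECG/EGM generator with exported ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
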