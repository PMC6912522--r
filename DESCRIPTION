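Package: patbp
Title: Pulse Arrival Time Based Beat-by-Beat Blood Pressure Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for beat-by-beat extraction of pulse arrival
    time (PAT) and pulse transit time (PTT) features from time-synchronized
    ECG, finger photoplethysmogram (PPG) and invasive arterial blood
    pressure (ABP) waveforms, and for calibrated linear estimation of blood
    pressure from those features. Includes nonlinear baseline removal,
    Pan-Tompkins R-peak detection, moving 10-beat ensemble averaging,
    fiducial detection on ABP and PPG (valley, peak, maximum derivative and
    intersecting-tangent points), plausibility gating of per-beat features,
    per-subject correlation analysis, a mean-calibrated pooled linear blood
    pressure model, and evaluation against the AAMI, BHS and IEEE 1708
    blood pressure monitor standards. A seeded synthetic ECG/PPG/ABP
    waveform generator with analytic per-beat ground truth makes every
    stage testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
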