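Package: segclock
Title: Delayed-Coupling Oscillator Models and Measurement Procedures for
    the Zebrafish Segmentation Clock
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis chain for zebrafish segmentation-clock
    experiments in which Delta-Notch coupling is perturbed.  Implements a
    delayed-coupling phase-oscillator model of the presomitic mesoderm in a
    co-moving frame (steady time-periodic wave patterns, linear stability by
    perturbation decay, coupling-strength x delay sweeps, and
    desynchronization/resynchronization of noisy oscillator populations), a
    Doppler-effect calculation that converts an anterior-wavelength change
    into a predicted segmentation period, quantification of one-dimensional
    gene-expression intensity profiles (peak detection, anterior wavelength,
    expression-onset position, expression length, neuron peak density,
    thresholded areas), somite-timing and boundary-defect scoring
    (regression periods, elongation rates, ALD/FRS/resynchronization rate),
    and efficiency-corrected qPCR copy-number estimation with loading
    calibration.  A synthetic-data module generates every input the chain
    consumes, with known ground truth, so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
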