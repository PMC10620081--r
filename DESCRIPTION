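Package: tistim
Title: Temporal Interference Stimulation Field Modeling and Envelope Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling transcranial temporal interference (TI)
    stimulation and analyzing depth-electrode recordings of interfering
    kHz-frequency fields. Builds layered voxel head phantoms with an
    embedded, parcellated deep target and orientation fields; solves the
    electro-quasistatic conduction problem (div(sigma grad phi) = 0) per
    electrode pair on the voxel grid with anisotropic conductivity
    tensors and current normalization; computes projected
    envelope-modulation and absolute-amplitude exposure maps with
    current-ratio steering sweeps and ROI summaries; and implements the
    envelope-analysis pipeline for multichannel recordings (Butterworth
    filtering, Hilbert-envelope extraction, epoch-wise modulation
    metrics, depth-gradient field estimates and interpolated maps).
    Includes generators for all synthetic inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    signal,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
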