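Package: eyeplaque
Title: TG-43 Dose Engine and Tumor DVH Analysis for Episcleral Eye Plaque
    Brachytherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dose calculation for episcleral (eye) plaque brachytherapy with
    low-energy photon-emitting seeds, following the AAPM TG-43U1 two-dimensional
    line-source formalism in homogeneous water.  Ships validated single-source
    parameter sets for the IsoAid IAI-125A (I-125) and IsoRay Cs-1 (Cs-131)
    seeds, parametric geometry generators for the 13-seed 16 mm COMS plaque and
    the 8-seed 16 mm OSU-NAG plaque on a spherical eye model, a superposition
    dose engine for arbitrary points and central-axis profiles, an air-kerma
    strength solver for decaying finite-duration implants, and a 1 mm spherical
    tally-lattice dose-volume histogram pipeline with V_x and D_v metrics for
    an ellipsoidal-dome tumor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
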