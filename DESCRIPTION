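Package: fetodose
Title: Internal Dosimetry of Thyroid Agents in a Pregnant Voxel Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for MIRD-style internal dosimetry of thyroid radiopharmaceuticals
    (I-131, I-123, Tc-99m sodium iodide/pertechnetate) administered to a pregnant
    patient. Builds synthetic pregnant-anatomy scenes from geometric primitives at
    ICRP 89/110 reference organ masses, voxelizes them with wall layering and
    exterior-layer mass adjustment, solves linear compartmental biokinetic models
    for cumulated activities across maternal thyroid-uptake levels (including an
    ICRP 53-style voiding-bladder model), builds radionuclide emission inventories
    with Fermi-shaped beta spectra, runs a simplified voxel Monte Carlo photon
    transport with kerma-approximation track-length scoring plus electron energy
    deposition, and assembles per-decay S-values into organ doses (mGy/MBq) with
    uptake sweeps, cumulated-activity provenance comparisons, whole-fetus dose
    summaries and voxel dose maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
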