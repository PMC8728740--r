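Package: memperturb
Title: Membrane Perturbation Analysis for Permeation-Enhancer Bilayer Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for molecular-dynamics trajectories of
    phospholipid bilayers doped with intestinal permeation enhancers.
    Reads multi-frame GRO/PDB trajectories with role-annotated topologies,
    detects expulsion, flip-flop and periodic-boundary crossing events,
    computes per-frame membrane structural metrics (area per lipid,
    phosphate-plane thickness, enhancer insertion depth), deuterium order
    parameters, lateral diffusion coefficients from mean squared
    displacement, water permeation counts, abundance-corrected fractional
    interaction matrices, and umbrella-sampling free-energy profiles via
    the weighted histogram analysis method with outside/inside partition
    ratios. A synthetic-data module generates bilayer trajectories with
    scripted events, Brownian walkers, orientation ensembles and biased
    umbrella samples with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml, jsonlite, bio3d
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
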