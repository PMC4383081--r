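Package: mtseam
Title: Pseudo-Helical Reconstruction of Kinesin-Decorated Microtubules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for cryo-EM analysis of kinesin-decorated
    microtubules: synthetic generation of seam-containing 13/14-protofilament
    lattices, decorated-filament density maps and CTF-modulated multi-frame
    movies with known ground truth; 2D micrograph operations (frame alignment,
    segment extraction, Radon in-plane angle estimation, phase flipping,
    compressed-filament diagnostics and 80 Angstrom layer-line detection);
    pseudo-helical single-particle reconstruction with per-filament seam and
    polarity search, 8 nm repeat remapping, direct-Fourier back-projection,
    wedge-mask protofilament symmetrization, tight masking, Fourier shell
    correlation and an iterative refinement driver; rigid-body subdomain
    motion analysis of atomic models (Kabsch superposition, axis-angle and
    screw decomposition, backbone RMSD, hydrogen-bond network and steric-clash
    scans); density-steered flexible fitting with a linearly ramped coupling
    restricted to backbone atoms and convergence-based frame selection; and
    stopped-flow mant-ADP release kinetics fitting (single-exponential traces,
    hyperbolic microtubule-concentration dependence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
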