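# mtseam

Desk-scale reimplementation of the computational pipeline behind
intermediate-resolution (5–6 Å class) cryo-EM studies of
kinesin-decorated microtubules, as an R package. It is aimed at method
developers and students who want every stage of such a study — image
formation, pseudo-helical reconstruction with per-filament seam search,
density-guided flexible fitting, rigid-body subdomain analysis, and
stopped-flow kinetics fitting — as small, testable, fully seeded code
with known ground truth, rather than as a cluster-scale production
system.

## What it implements

**Synthetic data with ground truth.** A parametric B-lattice microtubule:
`n_pf` protofilaments (12–15), helix start number 3, monomer rise 40 Å
(so an 80 Å tubulin-dimer repeat), one kinesin head per dimer at
`decoration_occupancy`. The dimer on protofilament *p* sits at azimuth
*p*·360/n_pf and axial offset *p*·(3·40)/n_pf; crossing all
protofilaments accumulates 120 Å = 1.5 repeats of rise, and the
resulting half-repeat register jump is the seam. Subunits are rendered as
soft Gaussian mixtures; movies are CTF-modulated projections
(`CTF(s) = −[√(1−A²)·sin χ + A·cos χ]`, `χ = πλΔz s² − (π/2)Cs λ³ s⁴`)
with per-frame drift and Gaussian noise. Stopped-flow fluorescence decays
follow `F(t) = offset + A·exp(−k_obs t)` with
`k_obs([MT]) = k_basal + k_max·[MT]/(K_0.5 + [MT])`.

**Micrograph operations.** Whole-frame alignment by iterative
cross-correlation with parabolic subpixel peaks; boxed-segment extraction
along filament paths; Radon-transform in-plane angle estimation; CTF
phase flipping; compressed-filament diagnostics (n-fold axial averaging);
power-spectrum layer-line detection — the 80 Å line appears only when
motors decorate the lattice.

**Pseudo-helical reconstruction.** Projection matching by Fourier central
slices (laterally oversampled trilinear interpolation), semi-exhaustive
orientation search with out-of-plane tilt restricted to ±15° of edge-on,
multi-reference protofilament-number classification, per-filament seam
and polarity determination over the 2·n_pf register candidates, exact
one-box-per-8 nm-repeat remapping, direct-Fourier back-projection into
even/odd half-maps, pseudo-helical symmetrization (all subunits averaged
onto one "good" protofilament, refilled through complementary soft wedge
masks that sum to one), soft tight masks, Fourier shell correlation with
the 0.143 resolution criterion, and a 20/15/12/10 Å ladder refinement
driver.

**Flexible fitting.** A coarse restrained-dynamics engine (reduced units,
k_BT = 1): harmonic restraints to the starting local geometry plus an
optional elastic network, with a map-derived steering energy
`−ξ(t)·Φ(x)` applied to backbone atoms only, where ξ follows a linear
ramp from zero. Convergence is monitored by per-group backbone RMSD
curves and the fitted frame is picked just after the initial rapid
transition. Follow-up stability runs keep positional restraints on
tubulin residues 1–380 and monitor hydrogen-bond persistence.

**Rigid-body subdomain analysis.** Kabsch superposition, axis–angle and
screw decomposition, per-subdomain rotation tables against a common
reference frame, backbone RMSD, heavy-atom hydrogen-bond checks
(d ≤ 3.5 Å, donor angle ≥ 120°), and van der Waals clash scans
(overlap ≥ 0.4 Å) with a cell-list accelerator.

**Kinetics.** Two-stage fitting: per-trace single-exponential nonlinear
least squares, then the hyperbolic `k_obs`-versus-[MT] fit returning
`k_max ± se` and `K_0.5 ± se`.

## Worked example

```r
library(mtseam)

## decorated vs undecorated filament: the 80 A layer line
spec  <- lattice_spec(n_pf = 14)                       # seam-containing
grid  <- list(n = rep(80, 3), voxel = 5)
vol   <- render_density(build_lattice(spec, 7), grid, 12, periodic_z = TRUE)
bare  <- render_density(build_lattice(lattice_spec(n_pf = 14,
           decoration_occupancy = 0), 7), grid, 12, periodic_z = TRUE)
img   <- project_volume(vol, rot = 37, tilt = 90, psi = 0)
img0  <- project_volume(bare, 37, 90, 0)
layer_line_scan(img, 80, 5)$significance    # 15.4  -> motor lattice present
layer_line_scan(img0, 80, 5)$significance   # 1.1   -> absent without motors
strongest_new_layer_line(img, img0, 5)$spacing  # 80  (Angstrom)

## stopped-flow kinetics from the hyperbolic ground truth
truth <- kinetic_truth(k_max = 0.26, K_half = 21.3)
concs <- truth$K_half * exp(seq(log(0.25), log(4), length.out = 8))
ds    <- simulate_kinetics(truth, concs, seq(0, 60, 0.25),
                           noise_sigma = 0.05, n_reps = 3, seed = 1)
fit_kinetics(ds)
#> Hyperbolic microtubule-activation fit
#>   k_max  = 0.2594 +/- 0.0033 1/s
#>   K_half = 21.36 +/- 0.7 uM

## a complete seeded reconstruction run (about 3 minutes)
report <- run_pipeline(default_run_config(seed = 1))
report$seam_recovery_rate        # 1     (10 of 10 filaments)
report$phantom_correlation_20A   # 0.943 (masked, 20 A band)
report$resolution_A              # 16.0  (FSC 0.143, half-maps)
```

A thin command-line wrapper lives in `inst/cli/mtseam.R`
(`Rscript mtseam.R run|simulate|kinetics|fsc ...`).

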