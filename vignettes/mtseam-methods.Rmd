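---
title: "Methods: pseudo-helical reconstruction and analysis of decorated microtubules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-helical reconstruction and analysis of decorated microtubules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, numerical choices and
limitations of the package, at the level of detail a user needs to judge
what a passing test suite does and does not demonstrate.

## The system and why a seam matters

A B-lattice microtubule of `n_pf` protofilaments (12–15) is a
pseudo-helical polymer: the 3-start monomer helix closes around the
cylinder with a total rise of `3 × 40 = 120` Å, which is not an integer
multiple of the 80 Å αβ-tubulin dimer repeat. One inter-protofilament
boundary therefore carries a half-repeat (40 Å) register jump — the
seam. True helical averaging is impossible; instead all asymmetric units
are transformed onto a single "good" protofilament with the operators
(twist `360 / n_pf`, rise `3 × 40 / n_pf`), and the filament is rebuilt
from transformed copies blended through complementary wedge masks.
Because kinesin binds one motor per dimer, decoration imposes an 80 Å
axial period on top of the 40 Å monomer period, visible as a layer line
at 1/80 Å⁻¹ — present only when motors are bound, which is also what
makes filament polarity and the seam register identifiable in noisy
images.

## The synthetic generator defines the study conditions

`lattice_spec()` defaults: monomer rise 40 Å (dimer repeat 80 Å), start
number 3, protofilament radius 110 Å, supertwist 0, full decoration.
The measured axial repeat of a real dataset is never exactly 80.0 Å;
the default is the canonical convention, configurable. Whether 14-pf
filaments carry supertwist is likewise not fixed by the data this
package emulates; 0 is an explicit assumption. Imaging defaults follow
low-dose direct-detector collection at 300 kV: pixel 1.99 Å, ~15 e⁻/Å²
over 15 frames, defocus ≈ 1.5 µm, amplitude contrast 0.07, Cs 2.7 mm
(a typical instrument value, our choice). Noise is Gaussian — an
adequate approximation of shot noise at these doses and far cheaper
than full Poisson optics. Astigmatism, ice gradients, beam tilt and
dose-dependent damage are not modeled.

Subunits are rendered as three-Gaussian blobs (tubulin monomer ≈ 4 nm,
kinesin head ≈ 4.5 nm, weights proportional to mass). α- and β-tubulin
are rendered identically — at the resolutions simulated they are
indistinguishable — so an undecorated filament has an exact 40 Å axial
period and, deliberately, *no* 80 Å line. The kinesin blob is tilted
toward the plus end (axially asymmetric). This is not cosmetic: a
z-mirror-symmetric motor blob would make polarity formally
unidentifiable, because flipping the decorated lattice end-over-end then
maps it onto itself shifted by half a repeat. The real motor is likewise
asymmetric; the package's polarity determination, like the experiment's,
rests on the decoration.

Filament volumes are rendered with a z-periodic wrap (`periodic_z`):
the lattice is exactly periodic with one dimer repeat along the axis, so
a grid whose z-extent is an integer number of repeats represents a
seamless, effectively infinite filament. All default grids respect this
(e.g. 80 voxels × 5 Å = 5 repeats).

## Geometry conventions

Images are matrices `[row, col]`; at zero in-plane angle the filament
axis runs along rows ("vertical"), and in-plane angles are measured from
that axis, counter-clockwise positive. Orientations are (rot, tilt,
psi): rot is the azimuth about the filament axis, tilt the out-of-plane
angle (90° = edge-on; searches span ±15° about it), psi the in-plane
angle. In the alignment code psi is realized as a real-space rotation of
the psi = 0 projection — slicing the Fourier transform of a z-periodic
volume at an oblique in-plane angle would sample between its discrete
layer planes and alias, whereas in-plane image rotation is exact in the
sense that forward simulation and matching use the same operation.
Polarity "−" composes a 180° rotation about the image x axis (a proper
rotation — flipping a filament end-over-end — not a mirror).

## Projection, back-projection and their accuracy

Projections are Fourier central slices with trilinear interpolation on a
laterally 2× zero-padded volume transform (z is never padded, preserving
filament periodicity); against an exact rotated-lattice oracle a single
slice correlates at 0.999. Back-projection inserts each box's transform
as a central slice with trilinear gridding weights into the matching
laterally oversampled grid and normalizes by accumulated weights —
classic single-particle interpolation gridding without an iterative
correction.
The residual cost of this choice is a few-percent amplitude bias at
voxels where many slices cross; it is invisible inside the molecular
envelope but fills solvent regions (notably the microtubule lumen) with
low-level artifacts. Reconstruction quality is therefore always
assessed, as in the refinement itself, under the soft tight mask: the
noiseless 200-view phantom reconstruction reaches a masked real-space
correlation of 0.997 with the ground-truth map at the 20 Å band after
symmetrization (0.98 unmasked).

Half-sets split by even/odd repeat index. Neighboring repeats of one
filament share signal, so the halves are only quasi-independent — the
FSC is mildly optimistic at low frequency; the resolution numbers
reported by the synthetic runs should be read with that caveat.

## Seam and polarity determination

The seam register and polarity are one joint decision: rotating the
reference by `k × 360 / n_pf` moves the seam azimuth and shifts the
decoration register by `k × rise`, and flipping polarity is a proper
180° rotation about the image x axis. Three deliberate choices make the
decision robust at SNR 0.3:

* scoring uses the filament's segment *average* — segments of a straight
  filament share orientation and repeat phase (the projection is exactly
  80 Å-periodic along the axis), so the average is an equal-weight score
  sum with √n better SNR;
* the search is fully exhaustive over the azimuth circle (3° steps), the
  ±15° tilt window (5° steps) and both polarities, against a projection
  bank built once and reused across filaments — seeding the register
  candidates from a separate single-pass orientation estimate proved to
  be the dominant failure mode, because an azimuth error of a few
  degrees flips the decision to a neighboring register;
* the winning orientation is locally refined (0.5° azimuth, 1.25° tilt)
  before the register is read off as the winning azimuth expressed in
  protofilament sectors.

The winning register must beat the runner-up register by 2% of the score
(and clear an absolute score floor) or the filament is flagged
ambiguous; with noisy motors (as for poorly ordered mutant decoration)
margins shrink and flags become frequent — the flag is a confidence
statement, not an error. Segment shifts are searched within ±8 px,
which exceeds half a repeat (6.4 px at 5 Å/px) so the axial phase is
always reachable, while the azimuthal seam signature cannot be absorbed
by any shift.

## Refinement

Four rounds against references low-passed on the 20/15/12/10 Å ladder;
after each round the half-maps are reconstructed, symmetrized,
tight-masked (binarize a 30 Å-filtered copy at 20% of max, smooth with a
10 Å-HWHM Gaussian), and the masked map seeds the next round. Local
searches use per-filament candidate grids (shared bank per filament,
per-segment in-plane refinement) with steps 2/1/0.5/0.25° by round and
parabolic subpixel shifts. The driver aborts if the mean score drops
more than 15% between rounds; moderate drops are expected at round 2
because the starting reference (rendered from the known lattice and
filtered to 20 Å) is cleaner than any reconstruction from noisy data.
The wedge masks are raised-cosine tents of full width `2 × 360 / n_pf`,
an exact partition of unity, so recombination introduces no amplitude
seams.

Default desk-scale problem size: 10 filaments × 20 repeats (200 boxed
8 nm repeats) at SNR 0.3 on an 80³ grid at 5 Å/voxel; the full run
takes about three minutes on one CPU, recovers seam and polarity for
all filaments, and reaches a masked phantom correlation of 0.94 at the
20 Å band. The unit-test suite uses 64³ grids and fewer repeats; sizes
are stated in each test.

## Repeat remapping and sub-frame refinement

`remap_repeats()` fits a smooth centerline through the per-segment axis
points (smoothing spline in arc length; a straight line for short
filaments), recovers the axial lattice phase as the circular mean of
(arc position + axial shift) modulo 80 Å, and extracts exactly one box
per repeat; repeats extending off-image are dropped and counted.
`subframe_refine()` re-refines three 5-frame sub-averages per segment
from the full-average parameters, falling back (flagged) when a movie
has fewer than 15 frames.

## Rigid-body subdomain analysis

Superposition is Kabsch (SVD with determinant correction), pairing atoms
by (chain, residue, atom name); axis–angle follows the closed form
`angle = acos((tr R − 1)/2)` with the screw point as the minimum-norm
least-squares solution of `(I − R) p = t⊥`. Subdomain rotations are
measured after superposing both states on a common frame — the anchor
chain or an unmoved subdomain. The frame matters: a whole-model
superposition distributes a subdomain's rotation into the frame and
under-reports it by several degrees, which is why the functions require
an explicit frame selection.

The subdomain residue ranges shipped in `default_subdomains()` split the
motor domain at the junction between the P-loop-anchoring and
switch-II-anchoring halves of the central β-sheet (N-terminal: 1–90,
100–150, 300–340; upper: 151–235; lower: 236–299). These boundaries are
a calibrated package default, not a published table, and should be
re-calibrated against states with known rotation magnitudes before use
on new models — the package's synthetic motor scaffold
(`synthetic_motor_model()`, clearly labelled synthetic) exists exactly
for that: states constructed with 22°/11°/3° subdomain rotations are
recovered to machine precision. Deposited experimental coordinate pairs
can be analyzed with the same functions once downloaded; the package
ships no third-party coordinates.

Hydrogen bonds use heavy-atom criteria (donor–acceptor ≤ 3.5 Å, donor
angle ≥ 120° via the donor's bonded heavy atom, angle skipped when the
antecedent is absent — EM-derived models often lack hydrogens and some
side chains). The default roster covers the closed switch-loop network
(Y138–E250, R203–E236, N255–E236 backbone, K91–D231). Clash scans use
standard van der Waals radii and a 0.4 Å overlap threshold; the
cell-list path is verified against the all-pairs reference.

## Flexible fitting

The engine deliberately replaces all-atom explicit-solvent molecular
dynamics with overdamped Langevin dynamics in reduced units (k_BT = 1,
lengths in Å): the protocol logic — a linearly ramped steering coupling,
backbone-only steering, convergence-based early-frame selection — is the
implementable contribution; force-field physics is out of scope. The
energy is

* harmonic restraints to the starting local geometry: chain bonds
  (k = 20), next-neighbor distances (k = 5), and an elastic network
  (8 Å cutoff, k = 1 by default) that preserves tertiary structure;
* optional positional restraints (default tier k = 20, the
  kcal/mol/Å-class restraint expressed in reduced units);
* the steering term `−ξ(t) Φ(x)` on the steering selection only, where
  Φ is the map low-passed at 6 Å (suppressing noise beyond the
  resolution support), clamped non-negative and rescaled to [0, 1];
  atom weights are uniform.

ξ ramps linearly from zero over 5000 steps by default (dt = 0.01). The
ramp length echoes the shape, not the physical duration, of a
nanoseconds-scale ramp; 5000 steps is the desk-scale choice that keeps a
fit under half a minute while the stability bound `k·dt < 1` holds for
the default springs. Integration instability, not physics, is the
constraint ruling out stiffer springs at this dt. The trajectory aborts
if a steered atom leaves the grid or the energy diverges — both are
diagnostics of overfitting-scale couplings.

Frame selection smooths the RMSD-versus-time curve with a 5-frame moving
average and returns the first frame where the derivative falls below 10%
of its peak and stays there for 10% of the trajectory — "immediately
after the initial rapid transition". Flat curves return the first frame
(flagged); curves that never plateau return the last frame (flagged
`no_plateau`): with a clean self-rendered target the fit ends in a
plateau, but a continuing ramp keeps pressing atoms into density, the
overfitting signature the early-frame selection exists to avoid.

Known-answer recovery (the package's calibration fixture): a 15° rotation
of the upper subdomain of the synthetic scaffold, fitted against the
target-rendered map (σ = 3 Å per bead), is recovered to within 2° with
final RMSD ≈ 0.5 Å, using ξ_max = 60, 6000 steps, dt = 0.005, elastic
network k = 5. Recovery quality is resolution-limited: inside a 6 Å-class
density basin the gradient vanishes and the last degrees of rotation are
recovered by the restraints' rigidity, not the map — with subdomains that
interpenetrate (many cross-subdomain network pairs) the same fit stalls
several degrees short. That behavior mirrors the real method's
sensitivity to how rigid-body-like the moving unit is.

## Kinetics

Two-stage fitting, as is standard for stopped-flow data: per-trace
nonlinear least squares of `offset + A·exp(−k t)` (Levenberg–Marquardt,
start values from a log-linear regression of the baseline-subtracted
trace), then unweighted least squares of
`k_obs = k_basal + k_max [MT]/(K_0.5 + [MT])`. `k_basal` is fixed at 0
by default (basal release is qualitatively small) with `fit_basal` to
free it. Constant traces are flagged unidentifiable; datasets whose
concentrations all sit below `K_0.5` flag the half-saturation constant
as poorly determined. The synthetic design for the acceptance check —
8 concentrations spanning 0.25–4 × K_0.5, 3 replicates, 5% amplitude
noise — is the package's fixture choice; the concentration series of the
original measurement is not printed anywhere we could adopt it from.

## Degenerate inputs and tie-breaks

Protofilament classification breaks exact score ties toward the lower
count, at both segment and filament (majority-vote) level. Phase
flipping leaves the zero-frequency term untouched and maps exact CTF
zeros to +1. `resolution_at()` returns Nyquist with a `no_crossing`
attribute when the FSC never drops below threshold. Empty tight masks
(threshold above the maximum) and all-zero steering maps are errors, not
silent passes. Segment extraction warns and returns an empty stack for
paths shorter than one box.

## Known limitations

* Interpolation-gridding reconstruction without apodization correction:
  unmasked solvent-region artifacts at the few-percent level; all
  quality metrics are defined under the refinement mask.
* Half-set splitting by even/odd repeat shares signal between halves;
  FSC resolution estimates on synthetic data are mildly optimistic.
* The CTF model is astigmatism-free and defocus is taken as known;
  defocus estimation is explicitly out of scope.
* The flexible-fitting engine has no electrostatics, solvent, or
  temperature/pressure coupling, and no claimed equivalence between its
  dimensionless coupling and any production MDFF scale factor.
* Polarity determination requires decoration; undecorated filaments are
  polarity-degenerate by construction (and nearly so in reality).
* Supertwisted (non-integer-start) helical search, Bayesian refinement,
  per-particle defocus refinement and handedness determination from tilt
  pairs are not implemented.
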