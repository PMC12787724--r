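---
title: "Nanorod diffusion in cross-linked networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanorod diffusion in cross-linked networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`netrod` simulates coarse-grained nanorods diffusing through a cross-linked
polymer network and measures their translational and rotational dynamics.
This vignette documents the model, the estimators, the numerical choices, and
what the package's synthetic validation does and does not establish about
real systems.

All quantities are in reduced Lennard-Jones units: lengths in the bead
diameter sigma, energies in kBT, masses in the bead mass m (= 1 throughout),
and time in tau = sigma * sqrt(m / kBT).

## The coarse-grained model

The system is a bead-spring model with four energy terms.

**Pair repulsion.** All bead pairs interact through the Lennard-Jones
potential U(r) = 4 eps ((sigma_ij/r)^12 - (sigma_ij/r)^6), truncated at
2.5 sigma_ij and shifted so the energy vanishes at the cutoff (the force is
that of the unshifted form). The well depth eps = 0.1 kBT makes the
interaction essentially repulsive, representative of sterically stabilized
(e.g. PEG-coated) nanoparticles in soft matrices. Pair diameters are
sigma_cc = sigma_nn = 1 sigma within the network and within rods; the
rod-network diameter sigma_cn is 2 sigma for *thin* rods (effective rod
diameter 3 sigma by Lorentz-Berthelot) and 2.62 sigma for *thick* rods,
which doubles the effective cross-sectional area. Enlarging only the
rod-network diameter keeps a linear bead chain while giving it a rod-like
excluded volume; rod-rod pairs keep sigma = 1 for both classes. Pairs joined
by a bond (1-2 pairs) are excluded from the LJ sum; 1-3 pairs are not.

**Bonds.** Adjacent beads are joined by U(r) = kb (r - r0)^2 with
kb = 25 kBT/sigma^2 and r0 = 1 sigma. Note the convention: no 1/2 prefactor
(the LAMMPS `harmonic` convention), so the effective spring constant is 2 kb.

**Angles.** Chain stiffness comes from U(theta) = ka (theta - pi)^2 on
consecutive bead triples, again without the 1/2 prefactor. The network uses
ka = 250 kBT/rad^2 along straight strand interiors. Rod stiffness ka is the
central control parameter: 250 (rigid), 25 (semiflexible) and 2.5 (soft)
kBT/rad^2. No angle term spans a network junction — a 6-way node has no
well-defined collinear triple — and junction geometry is instead maintained
by the tethers.

**Tethers.** Every network junction is restrained to its lattice position by
a self-spring U = k |r - anchor|^2 with k = 1 kBT/sigma^2, which suppresses
collective network drift while leaving strand fluctuations free.

### Network and rod construction

The network is a periodic cubic lattice of mesh a_x = 6 sigma: a junction
bead on every node, each node joined to its +x, +y and +z neighbours by a
strand of five interior beads at 1 sigma spacing. For the production box of
48 x 54 x 48 sigma this yields 8 * 9 * 8 = 576 junctions, 1728 strands and
9216 network beads. (The bead count reported for the original realization of
this system is 9016; its construction procedure is not fully specified, so
`netrod` defines the deterministic nodes-plus-uniform-strands discretization
above and documents the 200-bead difference rather than reverse-engineering
it. The builder is parameterized so an alternative discretization can be
swapped in.)

Rods are straight chains of N beads at 1 sigma spacing, inserted at seeded
random positions and orientations; a placement is rejected if any rod bead
falls within 0.9 sigma_ij of an existing bead (minimum image), which keeps
initial forces modest. The rod count keeps the total rod-bead budget fixed —
about 800 thin or 400 thick beads in the production box, scaled by box
volume for smaller boxes — so the rod volume fraction is constant across rod
lengths N = 10, 15, 20, 25.

## Langevin dynamics

Beads follow m r'' = -grad U - m zeta r' + F_R(t) with zeta = 1/tau and
T = 1 kBT. The random force obeys the fluctuation-dissipation theorem;
discretized per component and step its variance is 2 m zeta kBT dt (with
m = 1; stating the mass factor makes the m != 1 generalization unambiguous).
The integrator is the Gronbech-Jensen-Farago (GJF) splitting at
dt = 0.005 tau, chosen for its accurate configurational sampling at finite
time step; at zeta = 0 it reduces exactly to velocity Verlet, which is how
the NVE energy-conservation check is run. Velocities are initialized from
the Maxwell-Boltzmann distribution. Kinetic temperature is measured with the
half-step velocity (x_{n+1} - x_n)/(sqrt(b) dt): the GJF on-site velocity
systematically under-reads the temperature of stiff modes by O((omega dt)^2)
— about 2 percent here because of the ka = 250 angle terms — while the
half-step estimator samples kBT exactly for harmonic modes at any stable
time step.

Neighbour search uses a Verlet pair list with a 0.4 sigma skin (tunable),
rebuilt whenever the two largest per-bead displacements since the last build
sum past the skin. Each species-pair block is searched with its own cutoff,
which matters because the thin-rod rod-network cutoff (5 sigma) is twice the
network-network one. At the package's working system sizes (up to a few
thousand beads in boxes of 12-24 sigma, with cutoffs comparable to the cell
size a cell list would use) a direct O(N^2) rebuild over type blocks is
faster and simpler than a cell list; the all-pairs equivalence is verified
against an independent R oracle in the test suite. One seeded xoshiro256++
stream drives the noise, so a trajectory is bitwise reproducible from its
seed; replica campaigns use seeds seed+0, seed+1, ... mirroring independent
parallel runs.

Trajectories store *unwrapped* coordinates (the builder keeps wrapped
positions with integer image counts, so either view is exactly recoverable),
which is what every displacement statistic below consumes.

## Observables

`extract_rod_series()` reduces a trajectory to per-rod series: centre of
mass, squared end-to-end distance, the gyration-tensor eigenvalues
lambda1 >= lambda2 >= lambda3 (in the 1/N normalization, so their sum is the
squared radius of gyration), and the major axis.

**Major axis.** The unit eigenvector of the gyration tensor with the largest
eigenvalue. Rods are apolar (e and -e are equivalent), so the sign is fixed
by continuity: each frame's axis is flipped to have a non-negative dot
product with the previous frame's; the first frame points along the
end-to-end vector. For nearly degenerate tensors (lambda1 close to lambda2,
strongly coiled soft rods) the continuity rule is also the tie-break.

**MSD and its decomposition.** MSD(t) = <|r(t0+t) - r(t0)|^2>, averaged over
rods and time origins. The decomposition projects each displacement onto the
body frame *at the origin time t0* — e_par(t0) and a deterministic
right-handed perpendicular pair e_perp1(t0), e_perp2(t0) — and the axes are
not re-tracked during the interval. Any rotation of the perpendicular pair
about the axis leaves their summed contribution invariant (verified in the
tests), so the arbitrary in-plane orientation is immaterial. Two
perpendicular summaries are exposed: `perpendicular`, the average of the two
components (the curve conventionally plotted against the parallel MSD), and
`perp_plane`, their sum — the full in-plane squared displacement. The
diffusion-coefficient relations are D = MSD/(6t), D_par = MSD_par/(2t) and
D_perp = MSD_perp_plane/(4t): the 2D relation must see the full in-plane
displacement, not the per-component average, or it recovers half the true
D_perp.

**Anisotropy.** A(t) = 3 MSD_par / MSD - 1, bounded in [-1, 2]: 0 for
isotropic diffusion, 2 for purely axial motion, -1 for purely transverse
motion.

**Anomalous exponent.** alpha(t) is the local least-squares slope of log MSD
vs log lag over a sliding window of 5 grid points (the grid is log-spaced at
30 points per decade), reported at the window-centre lag.

**Non-Gaussian parameter.** alpha2(t) = <r^4>/((1 + 2/d)<r^2>^2) - 1 with
d = 3 for the full displacement, d = 1 for the parallel projection and d = 2
for the in-plane displacement. It vanishes for Gaussian displacements and
grows positive under dynamic heterogeneity.

**Rotation.** Per saved frame the rotation increment has magnitude
acos(e(t+dt).e(t)) — after flipping the later axis when the dot product is
negative, the apolar convention — and direction along e(t+dt) x e(t), the
instantaneous rotation axis. Their cumulative sum phi(t) is the rotational
analogue of an unwrapped coordinate; MSAD(t) = <|phi(t0+t) - phi(t0)|^2>,
and Drot = MSAD/(4t) for the rod's two rotational degrees of freedom. The
analyzer warns when the median per-step rotation exceeds 0.2 rad and refuses
above a 99th percentile of pi/4, where the acos map aliases. The rotational
non-Gaussian parameter alpha2_rot = 3<dphi^4>/(5<dphi^2>^2) - 1 keeps the
3D-form 3/5 coefficient while Drot keeps the 2-DOF normalization — both
conventions implemented exactly as stated, and dphi(t) is read as the
magnitude of the net rotation-vector difference over the lag (not pooled
per-step increments). The MSAD is insensitive to the cross-product sign
convention.

**Fits.** D, D_par, D_perp and Drot come from ordinary least-squares slopes
of the corresponding curves over a stated time window divided by 2d. At
production scale the conventional window is 1e5-4e5 tau; at desk scale the
automatic window takes the final decade of lags where alpha(t) > 0.9
(falling back to the final decade of the grid), and the window used is
always recorded in the fit object. Power-law scalings (D ~ N^l, Drot ~ ka^l)
are least-squares fits of log y on log x.

## The ideal rigid-rod generator

`generate_rod_oracle()` produces ground-truth trajectories with prescribed
body-frame diffusivities: per frame the orientation is rotated by Gaussian
angular increments of variance 2 D_rot dt about two axes perpendicular to
the current major axis (an exact Rodrigues rotation, so the axis stays
unit-norm without renormalization bias), and the centre of mass takes
Gaussian steps of variance 2 D_par dt along the axis and 2 D_perp dt along
each perpendicular direction. Frame spacing should satisfy
D_rot * dt < 0.01 rad^2 so the small-angle update is valid. The output is a
`rod_series`, so oracle data and MD data feed the identical analysis path —
this is what makes every estimator testable against known inputs, e.g.
recovery of (D_par, D_perp, D_rot) = (0.4, 0.1, 0.01) to within 5 percent,
the exact A(t) = 2 axial limit, and the alpha2 -> 0 Gaussian limit.

When fitting body-frame diffusivities from oracle (or any) data, the fit
window must sit well below the rotational decorrelation time 1/(4 D_rot):
beyond it the origin-frame projection mixes parallel and perpendicular
motion and both estimates relax toward the isotropic average
(D_par + 2 D_perp)/3 — itself a useful long-lag check.

## Problem sizes and what the validation shows

The full production campaign behind the scientific results (1e8 steps, five
replicas, 24 systems in the 48 x 54 x 48 sigma box) is cluster-scale. The
package's own tests and the acceptance script run the same pipeline at desk
scale, a deliberate choice of problem sizes:

* equipartition and NVE checks on a complete 12^3 sigma network with rods
  (1e5 steps);
* free-particle checks against the closed-form Langevin MSD
  6 kBT/(m zeta^2) (zeta t - 1 + e^(-zeta t)) with 1000 beads;
* oracle recovery with 500 rods and 1e4 frames;
* qualitative trend checks (D decreasing with N; strong anisotropy and
  perpendicular-dominated heterogeneity for rigid rods) in an 18^3 sigma box
  with the volume-scaled rod budget, 2 replicas, 8e5 production steps for
  rigid cells (long rigid rods are transiently super-diffusive along network
  channels, so their apparent D ordering only settles beyond ~1e3 tau) and
  2.4e5 for soft cells;
* the 3D alpha2 peak-lag measurement for thin N = 10 rods in a 24^3 sigma
  box (volume-scaled budget of 9 rods), 1e5 equilibration + 4.2e5 production
  steps, two replicas, with the peak located on a 5-point running mean of
  the log-grid curve.

These runs exercise every code path at full fidelity but shorter time scales
and smaller rod counts than production, so they validate the *estimators*
and the *qualitative* physics (trends, limits, identities), not the printed
production-scale scaling exponents (D ~ N^-1.5 for soft thin rods,
D_perp ~ N^-2/N^-5, Drot ~ N^-3/N^-6, Drot ~ ka^l), which need the full
campaign to pin down numerically. The generator emulates ideal rigid-rod
kinematics and the MD emulates the modelled network; neither captures
hydrodynamic interactions, explicit solvent, polydisperse or defective
network topologies, or attractive rod-network chemistry — all outside the
model by construction.

## Numerical notes and degenerate inputs

* Lags beyond the series length are dropped, never padded; lags with zero
  second moment are dropped from ratio statistics (A(t), alpha2).
* Time origins are capped (default 1e4 per lag) by uniform subsampling.
* The anisotropy and exponent estimators require a common lag grid and
  positive MSD values; non-positive values are excluded before taking logs.
* Overlapping beads (r < 1e-6 sigma) and degenerate angle geometries abort
  the force evaluation with an informative error; non-finite coordinates
  abort the integrator with the step index.
* `fit_D` refuses windows holding fewer than 3 lags; `fit_scaling` requires
  at least 2 strictly positive points.
* The insertion loop errors after 1e5 failed attempts for a rod, naming the
  rod index.

## Reproducing the shipped numbers

`scripts/acceptance.R --seed S --out results/acceptance.json` regenerates
every validation quantity from scratch with seeds derived from S; the test
suite (`testthat::test_dir("tests/testthat")`) covers the same ground plus
the per-operation oracles. The README shows a worked desk-scale example with
the numbers it prints.
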