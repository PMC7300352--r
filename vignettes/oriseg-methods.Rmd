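---
title: "Entropy-driven chromosome segregation: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-driven chromosome segregation: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`oriseg` studies whether purely entropic repulsion between two confined ring
polymers is sufficient to segregate a replicating bacterial chromosome, and
provides the single-particle track analysis needed to compare such
simulations with fluorescence time-lapse data of labelled replication
origins. This vignette is the package's own account of the model, the
numerical algorithms, and the places where a design decision had to be made.

## The physical model

The chromosome (about 4 Mb) is coarse-grained into a ring of `N = 80` blobs
of compacted DNA, roughly 50 kb each, consistent with reported topological
domain sizes. Each blob is a sphere of diameter `d_b`, the basic length unit;
`43 d_b` equals the 3.23-micron newborn cell length, hence
`d_b = 0.075 um`. All energies are in units of `k_B T`.

Three purely repulsive interactions define the energetics:

* **Blob-blob repulsion** is a screened-Coulomb (Debye-Hueckel) form,
  `U(r) = eps (d_b / r) exp(-r / d_b)`, with `eps = 1 k_B T` by default.
  This soft repulsion is the coarse-grained excluded volume between DNA
  blobs; it is what drives entropic demixing of the two rings. For partly
  grown blobs the effective diameter is the sum of the two bead radii, so a
  new bead interacts more softly until it reaches full size (mid-growth
  interactions are not otherwise constrained; scaling the length parameter
  with the bead size is the minimal consistent choice).
* **Wall confinement** uses the Weeks-Chandler-Andersen potential — the
  repulsive branch of Lennard-Jones, cut at `2^(1/6) sigma` and shifted by
  `0.25 * 4 eps` so it vanishes continuously at the cutoff — applied to the
  distance from the bead centre to the nearest point of the cylindrical
  wall (the lateral surface and both flat end caps), with `sigma` equal to
  the bead radius.
* **Bonds** are harmonic springs of rest length `d_b`. The spring constant
  is matched so that the elastic energy at extension `d_b` equals the
  blob-blob repulsion at separation `d_b`:
  `0.5 k d_b^2 = eps e^{-1}`, i.e. `k = 2 eps e^{-1} / d_b^2 = 0.7358`,
  which prints as the conventional `0.74`. Dimensionally `k` carries
  `k_B T / d_b^2` (a spring constant), whatever typography suggests
  elsewhere.

The cell is a cylinder with the long axis along x, initially
`3.23 x 0.42 um` (length x radius), growing linearly during replication to
`5.10 x 0.45 um`. The printed endpoint dimensions are taken as exact; note
they give a volume ratio of about 1.8, not exactly the qualitative
"doubling". Beads cannot penetrate the wall.

## Langevin integration

Equations of motion are integrated with a velocity-Verlet Langevin scheme at
time step `dt = 0.01 tau` and friction `gamma = 5` in reduced units
(`sqrt(m_b eps)/d_b`; bead mass `m_b = 1`). This friction makes the motion
overdamped — the velocity autocorrelation time `m_b/gamma = 0.2 tau` is tiny
compared with any interval of interest. Chromosomal blob motion in vivo is
overdamped, and results are insensitive to moderate variations of `gamma`.

The specific splitting used is BAOAB: half force kick, half drift, an
*exact* Ornstein-Uhlenbeck friction-plus-noise substep, half drift, half
kick. It is the standard modern member of the Langevin velocity-Verlet
family, satisfies fluctuation-dissipation by construction, and has very
small configurational sampling bias at finite `dt`. The thermostat checks in
the test suite (kinetic temperature within 5%, harmonic-dimer bond-length
statistics against a numerically integrated Boltzmann density) hold at the
default step size.

Numerical choices worth knowing about:

* **Pair cutoff.** The screened repulsion decays as `exp(-r/d_b)`; it is
  truncated at `6 d_b`, where it has fallen below `5e-4 k_B T` (forces of
  the same order), negligible against thermal forces of order unity. A
  Verlet neighbour list with a `1 d_b` skin, rebuilt every 10 steps, keeps
  the force loop near-linear in bead number; typical bead displacement over
  10 steps is well under half the skin.
* **Reproducibility.** The integrator uses its own PCG32 counter-seeded
  generator (Box-Muller normals), so a `(config, seed)` pair determines the
  trajectory bit-for-bit, independently of R's RNG state and platform.
* **Wall safety.** The WCA wall length scale equals the bead radius, so a
  *part-grown* bead (radius down to `0.05 d_b`) sees a very thin repulsive
  layer and could overshoot it within one step. Walls are impenetrable by
  construction, so the integrator reflects such rare crossings elastically
  (position mirrored at the wall, normal velocity component flipped) instead
  of producing an unphysical escape or a force blow-up. For full-size beads
  at the default step the reflection never fires in practice.
* **Blow-up guard.** Total energy is monitored; if it exceeds a thousand
  times its initial value the run aborts, and the driver retries with a
  halved time step (up to three halvings) before declaring failure.

## Starting configuration

A closed self-avoiding ring is grown on a cubic lattice (lattice constant
`d_b`) from the minimal four-site square by kink insertion: a random bond
`a-b` is replaced by `a-u-v-b` with `u, v` the lattice neighbours of `a, b`
in a random perpendicular direction, rejecting moves that would multiply
occupy a site. This is the simplest growth scheme satisfying the stated
rejection rule. The origin of replication (*ori*) is bead 1 and the terminus
(*ter*) the contour-antipodal bead `N/2 + 1`.

The lattice ring is centred and scaled *isotropically* so every bead clears
the wall by at least `0.5 d_b`; uniform scaling avoids biasing the initial
elongation, at the price of compressed bonds and high initial repulsion.
That is exactly what the subsequent equilibration is for: `10^3` steps of
`0.01 tau` (i.e. 10 tau; the step count is the authoritative figure) with
per-step energy logging. Stationarity is checked by comparing the third- and
final-quarter means of the total energy (warning above 10% drift; at the
80-bead standard size the drift is a few percent).

## Replication

Replication is divided into `N/2` duplication events evenly spanning a
rescaled 3,600 s. Two forks advance symmetrically from *ori* toward *ter*;
event `e` copies the template beads at contour offsets `e - 1` and `-e` from
*ori*, so the origin is duplicated at the first event (the tracked daughter
*ori* exists from the start of separation, as in the imaging experiments)
and the terminus at the final event where the forks meet. The partially
replicated molecule is maintained as a theta structure: the daughter arc is
bonded internally and, at each fork, to the template bead just ahead of that
fork; junction bonds advance with the forks and the final event closes the
daughter ring. Every bead then has exactly two bonds and the molecule
resolves into two disjoint 80-bead rings.

New beads appear with radius `0.1 d_b / 2` and grow linearly to `d_b / 2`
over the following duplication interval (newly synthesized DNA is assumed
compacted immediately). Two fork-placement models are implemented:

* **Track model** — forks travel with the chromosome: each new bead is
  placed at its template's position plus a random `0.5 d_b` offset.
* **Factory model** — replication happens at a fixed midcell position: the
  two templates of the upcoming event are drawn to within `1 d_b` of the
  factory by a transient flat-bottom harmonic tether (stiffness `10 k`,
  active only during that event's interval), and the new beads appear
  adjacent to the factory. The tether stiffness and the new-bead starting
  radius are free numerical choices, set stiff/small enough that the
  efficacy check (templates within `2 d_b` of the factory at duplication)
  and the energy guard hold.

Between events the whole system is integrated while the cell grows; the
default integration budget is 5,000 steps (50 tau) per duplication event,
so a full 80-bead replication covers 2,000 tau mapped affinely onto
3,600 s. Trajectories are sampled on a 10-s grid of that rescaled time,
mirroring the imaging interval.

## Segregation metrics

* **Degree of separation** — the overlap of the two chromosomes' x-extent
  intervals divided by the shorter extent; 0 means fully segregated.
* **Origin separation series** — per-frame `|x_ori1 - x_ori2|` and
  `|y_ori1 - y_ori2|` in micrometres; frames before the first duplication
  hold a structural zero (one shared origin).
* **Ensemble averages** — series are linearly interpolated onto a common
  grid; the summary reports pointwise means and standard errors
  (SD/sqrt(n)). Simulated ensembles are aligned at the start of
  replication, the closest analogue of aligning experimental pairs at their
  pairing onset.
* **Final normalized positions** — both origin x-positions at the last
  replication frame mapped through `(x + L/2)/L`; the larger and smaller
  are identified per run before averaging (the only labelling under which
  the two means are complementary about 1/2).
* **Step-size statistics** — signed per-frame increments of the long-axis
  separation, pooled over runs; leading structural zeros are dropped up to
  the last zero frame so the first real step is kept. The density uses
  Freedman-Diaconis binning, the Gaussian fit is maximum likelihood, the
  probability plot pairs empirical with fitted-normal quantiles, and the
  Shapiro-Wilk statistic is computed on at most 5,000 evenly thinned values
  (the test's implementation limit).

## Track analysis

The experimental-side pipeline consumes TrackMate-style spot tables (track
id, frame, x, y, intensity; 10-s frames). Origin pairs are followed from the
moment they are overlapping, detected either by proximity (two tracks closer
than 0.2 um) or by a fluorescence level at least twice that of a single
origin followed by a split into two tracks; the per-movie single-focus
reference level is the median spot intensity, the most robust available
stand-in for an undefined baseline. Ambiguous multi-way proximity is
resolved greedily by nearest distance, with a warning.

Per pair, the per-frame difference vector cloud is rotated onto the
orthonormal eigenvectors of its second-moment matrix about the mean; the
larger-variance direction ("longest extension") is the long axis, oriented
so the final frame's projection is non-negative, with a tie-break to the
image axes (and a warning) when the cloud is isotropic to within 1% of
variance. Because only within-frame differences enter, the entire pipeline
is invariant under rigid rotation and translation of the field, including
per-frame stage drift — the property that makes uncorrected stage motion
harmless.

Displacement-versus-lag curves average the *absolute* displacement
`|s(t + n dt) - s(t)|` over all tracks and all start frames (overlapping
windows; pooling maximizes use of the 10-s sampling). Absolute values are
used because the quantity is a distance moved; the lag curves of directed
motion are then exactly linear in the lag, and those of a pure random walk
follow the folded-normal mean, both of which serve as oracles in the tests.
Linear trends are ordinary least squares. The separation-speed estimator
fits the translocation window (from the detected onset to the first
approach to the plateau level) and reports the onset as the zero-separation
crossing of the fitted line, which is unbiased where a threshold crossing
would lag by threshold/speed.

## Synthetic tracks

There is no deposited imaging dataset, so the generator emulates the
phenomenology the pipeline assumes, with defaults chosen once to
represent the imaging conditions the pipeline targets: 10-s frames over 50 min movies; rod cells 3 um
long and 1 um wide scattered over the field; origins overlapped at midcell
for an exponential cohesion period (mean 8 min, truncated to the movie);
translocation toward the quarter-cell positions at a net 0.03 um/min
(separations of order a micron over tens of minutes), decorated
with Poisson bursts of exponential magnitude and geometric-duration
reversals ("separation and backward movement occurred repeatedly");
transverse Ornstein-Uhlenbeck confinement with 0.06 um stationary SD;
0.04 um localization noise (centroid precision, well below the 250-nm
optical resolution); rigid stage drift as a random-walk translation with
optional rotation; and a single merged ~2x-intensity focus during cohesion
when `merged_cohesion` is on. It does *not* simulate pixel-level imaging:
no point-spread function, no photobleaching, no detection failures — so
passing tests demonstrate the analysis chain, not robustness to
segmentation artifacts.

Estimator-consistency ("parameter recovery") tests run the full pipeline on
200 generated pairs and require the generating speed, mean cohesion
duration and transverse SD back within 10%, 15% and 15%. These tests use
parameter sets with bursts and reversals off and reduced localization
noise: bursts and reversals change the *net* separation rate by
construction (the "speed" parameter is the drift component alone), and
localization noise adds in quadrature to the transverse SD, so including
them would test arithmetic identities about the generator rather than the
estimators. The default parameter set is exercised separately for its
qualitative contracts (near-linear x lag curves, y movement restricted
below the confinement scale).

## Problem sizes

The shipped checks use ensembles of 20 seeded replication runs for the
factory and track models (the benchmark ensembles they are compared against
averaged 80 trajectories), 10 seeds per chain length in the overlapping-ring
scaling study over N = 20, 40, 80, and 200 synthetic pairs for recovery. These sizes were chosen as the smallest at which the
ensemble statistics are stable; standard errors are reported alongside every
ensemble mean.

## Known limitations and internal tensions of the benchmarks

* Two of the benchmark quantities this implementation is checked against —
  a mean final origin-origin distance of 0.5-0.6 um and mean normalized
  final positions of 0.61 and 0.38 — are mutually inconsistent: because the per-run larger and smaller positions differ by
  exactly the normalized separation, means of (0.61, 0.38) imply a mean
  separation of 0.23 of the cell length, about 1.1-1.2 um at the
  end-of-replication cell size. No single ensemble can match both. This
  implementation reproduces the normalized-position pair closely (about
  0.60 and 0.37 at 20 runs), and its ensemble-mean final separation is
  correspondingly about 1.2 um, not 0.5-0.6 um.
* The transverse origin separation necessarily rises from the structural
  zero at duplication to its confinement baseline (about 0.2 um in a
  0.45-um-radius cell). Statements that the y separation "does not change"
  hold only relative to that baseline, not as a sub-0.1-um bound from zero.
* At the default integration budget the two chromosomes are typically still
  partially overlapping in extent when replication completes (the origins,
  however, are well separated); complete demixing occurs during the
  post-replication phase.
* Two values are in circulation for the moment replication ends (3,300 s
  and 3,600 s); 3,600 s, consistent with the hour-long replication span,
  is used throughout.
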