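---
title: "Modeling PCH-nucleolus co-assembly: methods and design choices"
author: "nucleopch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling PCH-nucleolus co-assembly: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucleopch)
```

## The model

`nucleopch` implements a minimal coarse-grained model of how pericentromeric
heterochromatin (PCH) and the nucleolus co-assemble into their canonical
layered organization, together with the quantitative 3D image metrics used to
score that organization in microscopy data.

Four components live inside a spherical confinement representing the nucleus:

* **H** — PCH, a semiflexible bead-spring polymer with weak self-attraction.
  One bead represents ~5 kbp of chromatin and has diameter sigma ~ 30 nm, the
  model's length unit.
* **rD** — ribosomal DNA, a contiguous block occupying a fraction (default
  20%) of the middle of the PCH chain. It experiences good-solvent
  (excluded-volume) conditions but binds Fibrillarin.
* **F** — Fibrillarin, free diffusing beads with strong self-attraction; the
  proxy for the nucleolar dense fibrillar compartment.
* **X** — an amphiphilic protein with affinity for both the nucleolar phase
  (F) and PCH (H); the proxy for Pitchoune.

Energies are measured in units of the thermal energy kBT. Bonded neighbours
interact through a stiff harmonic spring `V = ks (r - sigma)^2` with
`ks = 100 kBT/sigma^2`. Chain stiffness is a harmonic-cosine bending term
`V = k_bend (1 + cos theta)`, zero for straight triples; with
`k_bend = 2 kBT` the measured tangent-correlation decay length of a free
chain is ~2 beads = 60 nm, the target persistence length. The bending
functional form is this package's choice: only the persistence length itself
is prescribed by the model, and the harmonic-cosine is the standard minimal
form that reproduces it.

Non-bonded pairs interact through a 12-6 Lennard-Jones potential. Attractive
pairs are truncated at `2.5 sigma`; pairs restricted to excluded volume use
`epsilon = 1 kBT` truncated at the minimum `2^(1/6) sigma` (WCA), where the
force vanishes continuously. Both modes are *cut and shifted* so the energy
is continuous at the cutoff; the shift leaves forces unchanged and makes
energies comparable across implementations. The spherical wall acts on the
gap `Rc - |r|` through the same purely repulsive shifted form.

### Parameter values

The confinement radius follows from the chromatin volume fraction
`phi = 0.1`: with the diploid genome (360 Mbp at 5 kbp/bead, NG = 72,000
beads) and bead volume taken at radius sigma/2,
`Rc = (NG / (8 phi))^(1/3) = 44.8 sigma`, i.e. the nominal 45 sigma. Note the
bead-radius convention: taking the full diameter as the radius would give
89.6 sigma, which is inconsistent with the nominal confinement size; the
sigma/2 convention is the one that reproduces it, and is what
`confinementRadiusFromPhi()` implements.

Protein bead counts come from number densities: `N = c * (4/3) pi Rc^3`, so
the reference Fibrillarin concentration `cF = 0.013 sigma^-3` gives 4,962
beads at full size.

The wild-type (+rDNA) interaction hierarchy, asserted at construction by
`plusRdnaMatrix()`:

| pair | epsilon (kBT) | mode |
|------|------|------|
| rD-F | 2.0 | attractive |
| F-F  | 2.0 | attractive |
| X-X  | 1.75 | attractive |
| F-X  | 1.5 | attractive |
| X-H  | 1.0 | attractive |
| H-H  | 0.35 | attractive |
| H-F, H-rD, rD-rD, rD-X | 1 (WCA) | excluded volume |

The X-X and X-H defaults are midpoints of the intervals that the hierarchy
`rD-F = F-F > X-X > F-X > X-H > H-H` leaves open; both are exposed in the
configuration. The rD-X pair is excluded-volume by choice (nothing
constrains it). `minusRdnaMatrix()` models rDNA deletion by switching rD-F
to excluded volume; its default raises X-H to 1.5 kBT = F-X, the boundary of
the regime (X-H >= F-X) in which the amphiphile forms a neocondensate inside
the PCH void. A weaker X-H is accepted with a warning.

## Dynamics

`integrateDynamics()` integrates underdamped Langevin dynamics with the
BAOAB velocity-Verlet splitting: friction enters as `gamma * mass`, the
Gaussian noise obeys fluctuation-dissipation, and a free bead diffuses with
`D = kBT / (gamma mass)` (verified to within a few percent by the
time-averaged mean-squared-displacement test). Defaults: `mass = 1`,
`gamma = 1`, `dt = 0.005` reduced time. The scenario and sweep runners use
`dt = 0.01`, which doubles the physical time sampled per step; at the bond
stiffness used here (`omega dt ~ 0.14`) the bond-length distribution
(sd 0.070 sigma vs the analytic 0.0707) and chain persistence length are
indistinguishable from the `dt = 0.005` results, which is the accuracy that
matters for the structural observables classified downstream.

Pair interactions use a cell-list-backed Verlet neighbour list (skin
0.4 sigma, rebuilt when any bead moves half a skin); the neighbour-list
forces equal the brute-force all-pairs evaluation to 1e-12 relative, which
the test suite asserts. A single RNG stream keyed by the seed drives noise
in fixed bead order, so identical seeds give bit-identical trajectories on
the same build.

Runs follow the staged protocol of `runProtocol()`: a short push-off with
per-bead force capping (to survive residual overlaps of the random start),
an equilibration segment, and a production segment with frame saving. The
initial state is a confined self-avoiding random walk for the polymer plus
uniformly placed free beads, push-relaxed to a minimum pair separation of
0.8 sigma.

## Observables and classification rules

"Condensed" is operationalized as: at least half of a species' beads belong
to one connected cluster (single linkage at 1.5 sigma, the first
coordination shell), sustained over the final three saved frames. The 0.5
boundary is inclusive. These constants are declared analysis choices — the
observable itself ("does this species form one body?") has no unique
quantitative definition.

Wetting of the Fibrillarin condensate by the amphiphile is scored on the
F-cluster surface: surface beads are those with fewer than 8 F neighbours
within 1.5 sigma (a cheap, rotation-invariant coordination criterion), and
coverage is the fraction of surface beads with an X bead within contact
range. Verdicts: below 0.1 coverage "none", 0.75 and above "complete",
otherwise "partial". The 0.1/0.75 cuts are declared, not fitted.

rDNA engulfment uses the fraction of rD beads inside the ball around the
F-cluster centre of mass with radius equal to the 80th percentile of the F
beads' radial distances (robust to stragglers): fraction >= 0.5 is
"interior" (rDNA condensed within the Fibrillarin body), below is
"wrapping".

`layeringVerdict()` combines these into one classification per
configuration, using radial medians of F, X and H about the F-cluster centre
(or the X centre when F is dissociated): **layered** requires
median_F < median_X < median_H with complete X coverage of F;
**neocondensate_in_H** requires the X cluster centre inside the H
condensate's radial extent with F farther from the H centre than X;
**dissociated** means the F-X centre separation exceeds the sum of the
clusters' radial extents. Verdicts additionally require the species involved
to be condensed, which keeps shuffled/mixed configurations classified as
"none". All verdicts are invariant under rigid motions of the configuration.

## Desk scales, protocols and their consequences

The full-size system (10,000 polymer beads plus ~10,000 proteins) is not the
regime in which a test suite can iterate, so the experiment runners operate
on scaled replicas produced by `scaleSystem()`: bead counts scale by `s` and
the confinement radius by `s^(1/3)`, preserving every number density and all
interaction strengths. The package uses two presets:

* **scale 1/64** (Rc = 11.25 sigma, ~310 beads) for the four-component
  organization experiments (wetting sweep, depletion series, the +/-rDNA
  scenarios) in the routine test and acceptance runs; scale 1/27 gives the
  same classifications at ~4x the cost and is the better choice for
  exploratory work.
* **single-component cells** for the Fibrillarin phase diagram at Rc = 15
  (dense end) and Rc = 30 (dilute end, where a larger box keeps enough beads
  at `cF = 0.0013`).
* **N = 400** for the chain-collapse sweep (see below).

One desk-scale limit deserves emphasis: the amphiphile count scales with
the system volume but the Fibrillarin surface it must coat scales with
volume^(2/3), so the amphiphile available per unit condensate surface falls
as scale^(1/3). At full size the amphiphile can coat the condensate several
times over; at 1/64 it is sub-monolayer after partitioning toward the PCH
phase, and the steady-state surface coverage plateaus near 0.4 at every
desk scale tested (1/64, 1/27 and 1/8, from dispersed and from
pre-assembled starts alike — while the F+X subsystem without PCH sustains
coverage ~0.9). Complete engulfment, and with it the strict "layered"
label, is therefore a full-scale phenomenon; at desk scale the verdicts
report the partially wetted steady state, and the organization phenotypes
are read from the scale-robust observables instead: the radial ordering of
the phases, the rDNA interior fraction, the F-X distance across the wetting
transition, and the PCH-Fibrillarin distance under amphiphile depletion and
rDNA removal.

Scenario production runs are a few hundred thousand steps (several thousand
reduced time units). These lengths were chosen as the point where the
classification observables (cluster fractions, radial medians, coverage)
stop drifting in pilot runs; they are documented here as the package's
operating sizes.

### Why the phase diagram uses a droplet-stability assay

The phase-diagram operation must decide, per (concentration, epsilon) cell,
whether Fibrillarin condenses. Starting from a dispersed gas this is a
*nucleation* problem, and at the dilute end it is rate-limited: at
`cF = 0.0013 sigma^-3` the critical nucleus implied by classical nucleation
theory at these interaction strengths is tens of beads and the barrier tens
of kBT, so no spontaneous condensation occurs on any simulable timescale —
not because the condensed state is unstable, but because it is kinetically
unreachable. Waiting for rare events would make the cell classification a
measurement of run length, not of the phase boundary.

`fibrillarinPhaseDiagram()` therefore defaults to a condensed start: each
cell begins from a compact droplet containing all F beads and asks whether
the droplet *survives* (largest-cluster fraction >= 0.5 sustained over the
final frames) or evaporates. Droplet evaporation is fast when the droplet is
unstable, so cells resolve in well-defined time; at `epsilon = 0` the
droplet explodes instantly, reproducing the trivial "no attraction, no
condensate" column. A dispersed start remains available
(`start = "dispersed"`).

This assay measures the *finite-droplet* stability boundary, which sits
above the bulk (infinite-system) binodal by the Kelvin correction: a droplet
of radius R tolerates an ambient density elevated by `exp(2 gamma v / R kBT)`
relative to a flat interface, and at desk scale the droplets are small
(R ~ 3-5 sigma). The measured thresholds are therefore upper bounds on the
bulk thresholds, and the shift grows as the concentration drops (smaller
droplets). In practice the dense-end threshold lands inside the reference
1.3-2.0 kBT band, while at the dilute end even 2.0 kBT does not sustain a
droplet at simulable sizes — the corresponding acceptance check is expected
to fail, and the test suite keeps it as an honest negative rather than
widening the criterion.

### Chain collapse

`pchCollapseSweep()` runs an isolated all-H chain in a generous confinement
over an epsilon_HH grid. "Collapsed" is declared when the mean radius of
gyration over the final frames drops below 0.6 of the athermal
(epsilon = 0) reference for the same chain. The coil-globule onset moves
down toward the theta point as the chain grows: at N = 200 the chain is
genuinely bimodal near the transition (pilot runs show excursions between
compact and swollen states) and the onset reads one grid step higher than
at N = 400, where both replicate seeds agree at every grid point. The
acceptance protocol therefore uses N = 400 with two seeds and a majority
rule; the onset carries a one-grid-step (0.05 kBT) uncertainty, and the
full-length chain (N = 10,000) is expected to sit slightly lower still.

## The synthetic nucleus-image generator

`generateNucleusVolume()` renders the four organizations observed in
embryos as multi-channel 3D volumes with exact ground truth: a nucleolus
sphere tightly enclosed by a PCH shell ("surrounded"), an elongated PCH body
at the nuclear edge ("extended", with controllable in-plane aspect ratio), a
compact PCH ball separate from the nucleolus ("compact"), and a hollow PCH
shell whose core is filled by a distinct protein channel ("void").
Foreground amplitudes sit on a dim nuclear background, degraded by additive
Gaussian noise; `generateNucleusTimeseries()` adds exponential
photobleaching for time-series metrics.

The generator emulates *geometry, contrast and noise* — the features the
image metrics actually consume. It does not emulate optical blur
anisotropy, depth-dependent attenuation, chromatic shift, or crowded fields
of touching nuclei. Metric tests against generated volumes therefore
validate the measurement code (segmentation, shell occupancy, distances,
shape, intensity traces) on known geometry; they do not certify performance
on real microscopy, where preprocessing choices (background radius, blur
sigma) matter and are exposed as parameters.

Thresholding implements Otsu (maximum between-class variance) and Yen
(maximum correlation criterion) from their defining criteria over a 256-bin
histogram; the test suite checks Otsu against exhaustive maximization and
against an independent library implementation. Connected components use
26-connectivity in 3D and 8 in 2D. "Centre of geometry" is the unweighted
mask centroid. Dilation uses a discrete ball; "dilated by 1 pixel" is one
unit-radius dilation step. The circularity trace uses a 4-direction
Crofton perimeter estimator — circularity values depend on the estimator,
so it is fixed and documented (`croftonPerimeter()`), and the square-mask
test pins its analytic value.

## Numerical choices and degenerate inputs

* Pair distances below 0.3 sigma evaluate at 0.3 sigma with the event
  counted (force capping); the staged protocol additionally caps per-bead
  forces during push-off only.
* A constant image has no histogram threshold: segmentation raises a
  degenerate-histogram error rather than guessing.
* A species that never condenses is measured on all its beads and flagged;
  an empty X population gives coverage 0, verdict "none".
* Collinear 2D masks floor the minor axis at the one-pixel width
  (2 sqrt(1/12) px) and set a flag.
* Ties: the condensation fraction boundary (exactly 0.5) is inclusive;
  cluster labels are deterministic by lowest member index.

## Known limitations

* No hydrodynamics, electrostatics, or explicit rRNA/transcription; the
  amphiphile is a single bead species with isotropic affinities.
* Desk-scale thresholds carry finite-size (Kelvin) shifts, documented above;
  quantitative comparison with full-scale simulations should use
  `scaleSystem()` at larger scales and expect thresholds to move down.
* The classification thresholds (0.5 condensation fraction, 0.1/0.75
  wetting, 0.5 interior fraction) are declared constants; conclusions that
  hinge on values near a threshold deserve replicate seeds.
* The image metrics assume isotropic-in-plane voxels and at most mild
  anisotropy in z (handled only in physical-distance conversions).
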