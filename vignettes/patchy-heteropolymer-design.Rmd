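---
title: "Designing patchy heteropolymers: models, protocol and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing patchy heteropolymers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(patchyfold)
```

## The scientific question

Proteins are the existence proof that a linear chain with a finite
alphabet of monomer chemistries can fold reliably into a unique compact
structure. Generic random heteropolymers do not: they collapse into
degenerate molten globules. This package implements a coarse-grained
laboratory for the question *what minimal ingredients make a
heteropolymer designable* — specifically, how many directional surface
patches per monomer, at what alphabet size `q`, convert a glassy
collapser into a folder.

## Models and energies

A chain of `N` hard beads (radius 1, the unit of length; energies in
`kB*T_Ref`) carries three interaction terms.

**Isotropic chemistry.** Non-bonded beads of types A and B interact via
a sigmoidal square well `eps_AB * (1 - 1/(1 + exp(2.5*(r_max - r))))`
with `r_max = 6`, the distance at which the energy is exactly half the
prefactor. The interaction is truncated at `r_max`; this discards the
outer half-tail of the sigmoid, which is the cutoff convention the well
shape was built around, and Metropolis sampling does not require a
continuous potential. The `q(q+1)/2` prefactors are drawn once per
system from a zero-mean Gaussian with standard deviation 0.33 — the
random chemistry of the alphabet. The hard core acts between non-bonded
bead *centers* at distance 2 (two touching unit beads); bonded
neighbours are instead restrained by their spring.

**Directional patches.** Every monomer carries the same arrangement of
surface patches along fixed body-frame axes: 1 axis, poles (2), an
equatorial equilateral triangle (3), a tetrahedron (4), an octahedron
(6), or the 10-point spherical code (gyroelongated square bipyramid,
obtained here by a deterministic one-parameter golden-section
maximisation of the minimum pairwise angle within that symmetry family).
Patch pairs on distinct monomers interact through a 10–12 well in the
patch-to-patch distance `R`, gated by `(cos(theta1)*cos(theta2))^2`
where `theta_k` is the angle between patch axis `k` and the
displacement; the minimum `-s*eps_p = -12.4 kBT` is reached for facing
patches at `R = sigma = 1`, i.e. bead centers 3 radii apart. With the
even exponent the sign convention of the displacement is immaterial. We
truncate at `R_cut = 3*sigma` without shifting: the neglected tail is
below 1% of the well depth, and shifting would silently change the
meaning of the standard parameter values. Patch interactions between bonded neighbours are
*included*; the bonded-pair exclusion applies only to the isotropic term
and to the g(r) analysis, which has its own explicit exclusion rule.
No valence cap is imposed — the angular gate is the only saturation
mechanism.

**Bonds.** FRC: a harmonic spring of stiffness 100 and rest length 2
between consecutive centers. FJC: the same spring between the forward
anchor point of bead `i` and the backward anchor point of bead `i+1`,
rest length 0 (surfaces touching). The spring parameters are a package
choice: stiff enough that bond-length fluctuations (sd ~ sqrt(T/100) ~
0.1) stay well off the g(r) analysis windows, and configurable. For the
FJC the anchors are antipodal in the 1-patch geometry; in the 2-patch
geometry the two patches and the two anchors together occupy the four
vertices of a tetrahedron — the standard arrangement for that case,
even though it breaks anchor antipodality.

Orientations are unit quaternions, renormalised after every update;
increments compose on the left (`q_new = dq * q_old`).

## Sampling

Metropolis Monte Carlo with four conformational moves (single-bead
displacement, single-bead rotation, crankshaft of an interior segment
about the axis through its end beads, rigid pivot of the chain tail) and
two sequence moves (point mutation, pair swap). One sweep is `N` move
attempts per replica. Move amplitudes are tuned toward ~30% acceptance
during burn-in only, then frozen — tuning during measurement would
break detailed balance. Proposals that violate the hard core are always
rejected.

Replica exchange runs one chain per ladder temperature — the standard
ladder is the 16-temperature set
`3, 2.5, 2, 1.6, 1.4, 1.2, 1, 0.9, 0.8, 0.75, 0.7, 0.65, 0.6, 0.55,
0.5, 0.4` (units of `T_Ref`) — with nearest-neighbour configuration
swaps of probability `min(1, exp((1/T_a - 1/T_b)(E_a - E_b)))`,
alternating pair parity every sweep. We use plain replica exchange
rather than virtual-move variants: those are efficiency devices and
leave every equilibrium marginal unchanged, which is the property the
tests verify. All randomness flows from one master seed (one
`mt19937_64` stream per temperature slot plus one for swaps), making
every trajectory, and the full three-stage protocol, a pure function of
(configuration, seed). Incremental energies are resynchronised against
a full recomputation every 500 sweeps to eliminate floating-point
drift.

## The SEEK–DESIGN–FOLD protocol

Each stage runs `n_runs` independent simulations (10 in the standard
protocol; fewer for desk-scale work, with a note) and accepts its result
only if the runs' free-energy profiles *overlap within statistical
error*: on every jointly visited bin, each pair of runs must agree
within 3 combined standard errors and the total spread must stay below
1 kBT — the granularity at which the final classification is made.
Profiles are `F = -T ln H` from each temperature's own histogram
(DRMSD bin width 0.05), minimum-shifted, with Poisson errors
`T/sqrt(H)`; empty bins are masked, never interpolated.
Multi-histogram reweighting is deliberately omitted: at the problem
sizes this package targets, single-histogram estimates with explicit
per-bin errors keep the convergence criterion simple and honest.

**SEEK** samples conformations and sequences jointly. The cold
free-energy landscape is projected onto the *potential energy* — a
reproducible, parameter-light proxy for this under-determined step;
the target basin is in any case not unique, and other low-free-energy
structures can serve equally well. The basin is every sampled cold
state within 1 kBT of the global minimum, and the returned target is the
basin *medoid* under DRMSD distance (capped at the 150 lowest-energy
basin states), a stand-in for "the structure the most sequences fold
into" that is deterministic given the seed.

**DESIGN** freezes the conformation and samples sequences. It returns
the minimum-energy sampled sequence whose composition Shannon entropy is
at least `0.8 * ln(q)` — the heterogeneity constraint that prevents the
designed chain from collapsing onto a few monomer types (a homopolymer
can always lower energy but never folds uniquely). If no sampled
sequence qualifies the constraint is relaxed with a warning. On
exhaustively enumerable toys the result provably lands in the
brute-force optimum set (tested).

**FOLD** starts from the fully stretched chain with the designed
sequence frozen and histograms the DRMSD to the target at every ladder
temperature. The architecture is *designable* if the global minimum of
`F(DRMSD)` at any temperature lies strictly below the molten-globule
band — the DRMSD interval where the matched 0-patch baseline's free
energy is within 1 kBT of its own global minimum. A minimum exactly at
the band edge is classified not designable (the conservative reading of
the borderline case). Across architectures, the designable/not table
over `(patches, q)` brackets the conformational entropy per monomer:
`omega > ln(q_max)` where nothing folds, `omega < ln(q_min)` where
everything does (see `entropy_bounds()`).

## Analysis

**Order parameters.** `drmsd()` is `(1/N) sqrt(sum_{i<j} (|r_ij| -
|r_ij^T|)^2)` over unordered pairs including bonded neighbours — any
pair convention gives zero exactly at the target, and this one matches
the 1/N scale of the folding profiles. `rmsd()` performs optimal proper
superposition (Kabsch, reflections excluded, so mirror images of chiral
structures score above zero) with the same `1/N` prefactor; the
distance-like notation sometimes used for this quantity is resolved in
favour of superposition RMSD, since structures are aligned before
reporting.

**Radial distributions.** `radial_distribution()` histograms
center–center distances excluding pairs adjacent along the chain and
normalises by an *exact finite-system ideal gas*: the pair-distance
density of a uniform ball whose radius derives from the ensemble's mean
radius of gyration (`a = sqrt(5/3) <Rg>`). A uniform cloud therefore
gives `g = 1` on every bin with no boundary artefact. Bins near `2a`
have vanishing reference counts and can spike; the peak analysis
restricts its amplitude scale to the physically meaningful window.
Default bin width is 0.02 bead radii (0.1 Å for the protein C-alpha
variant); desk-scale ensembles of ~40 conformations are better analysed
at 0.1.

**The designability fingerprint.** `peak_area_ratio()` integrates g(r)
over the random-packing window (bead contact, fallback `[1.9, 2.6]`)
and the directional window (patch bonding, fallback `[2.7, 3.5]`) and
reports their ratio. In auto mode the curve is smoothed (3-bin moving
average), local maxima in `[1.8, 4.5]` are segmented between flanking
minima, and a maximum only counts as a peak if its prominence exceeds
10% of the window's amplitude — without this, counting noise in small
ensembles produces spurious "peaks". A dominant directional peak (small
ratio) is the structural fingerprint of designability, mirrored in real
proteins by the backbone hydrogen-bond distances that dominate C-alpha
g(r) curves (`protein_calpha_gr()`).

**"Most probable conformations."** `fold_ensemble()` ranks the stored
coldest-temperature snapshots by potential energy and keeps the 40
lowest-energy representatives that differ pairwise by more than 0.1
DRMSD — free-energy ranking with deduplication, our operational reading
of an ensemble definition that the method leaves informal.

## Problem sizes and what the tests show

The standard configuration is 50-mers, the full
16-temperature ladder, 10 independent runs per stage. The package's own
test and demonstration runs use desk-scale reductions chosen once:
20-mers on a 6-temperature subset `3, 2, 1.4, 1, 0.7, 0.4` with 2
independent runs of 6000 measured sweeps (2000 burn-in, stride 5) —
about half a minute per architecture on one core. At this scale the
4-patch, q = 20 chain already develops the directional g(r) peak at
r ≈ 3 that the 0-patch chain lacks (area ratio ~0.2 vs ~1), but folding
minima remain in the molten-globule region: resolving sharp folded
minima at DRMSD < 0.6, converged per-architecture area ratios, and the
full designability diagram over every (patches, q) pair requires
cluster-scale sweep counts.
Inter-run convergence warnings at desk scale are expected and honest:
they are the protocol's own signal that the landscape is under-sampled.

The synthetic fixture generator covers what the analysis code needs to
be provably correct — stretched and self-avoiding chains, uniform
ideal-gas clouds (flat-g oracle), two-Gaussian g(r) curves of known
areas, an ideal poly-alanine C-alpha helix with canonical rise 1.5 Å /
twist 100° / radius 2.3 Å. It does *not* emulate rugged folding
landscapes, real protein statistics, or inter-chain aggregation, so
green tests certify the estimators and the sampler, not biological
realism.

## Known limitations

* Single chains only; no inter-chain interactions or aggregation.
* Isotropic truncation at `r_max` leaves an `eps/2` step; irrelevant to
  Metropolis sampling but this potential should not be fed to molecular
  dynamics.
* The SEEK target-extraction rule (energy projection, 1 kBT basin,
  DRMSD medoid) is one defensible reading of an under-specified step;
  alternative low-free-energy structures can be equally good targets.
* `q` outside 3–20 is permitted only behind an explicit override, and
  the 0.33 interaction scale is not re-calibrated for it.
* Desk-scale runs under-sample by construction; treat their
  designability verdicts as qualitative.
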