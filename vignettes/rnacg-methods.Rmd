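---
title: "Coarse-grained RNA folding simulations with restraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained RNA folding simulations with restraints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnacg)
```

## The problem this package addresses

RNA function frequently depends on tertiary structure, and experimental
structures exist for only a small fraction of known RNAs. A widely used
strategy is to explore the conformational space of a reduced (coarse-grained)
chain model with Metropolis Monte Carlo sampling under a scoring function,
optionally biased by whatever structural information is available: a
predicted or probed secondary structure, known noncanonical contacts,
per-nucleotide chemical reactivities, or a partial 3D model whose known parts
are held fixed. `rnacg` implements that method layer — restraint handling,
sampling, and trajectory analysis — end to end, together with synthetic
fixture generators so every property of the pipeline can be demonstrated and
tested without external data.

## The coarse-grained representation

Each nucleotide is reduced to five beads: two backbone beads (P, C4') and
three base beads — the glycosidic nitrogen (N9 in purines, N1 in
pyrimidines), C2, and C6 (purines) or C4 (pyrimidines). Three base beads are
the minimum that pins both the position and the orientation of a base plane,
which is exactly what base-pair restraints need.

The reference geometry is idealized rather than fitted: base rings are
regular polygons with 1.39 Å bonds; a base pair of any Leontis–Westhof
family (edges W/H/S, cis or trans) is constructed by docking the two edge
directions at hydrogen-bond distance (2.9 Å between edge contact points);
the partner base is placed by the duplex dyad (a proper two-fold rotation in
the pair plane), which makes the two strands of a helix congruent. Helices
use an A-form-like rise of 2.81 Å and twist of 32.7° per rung, and backbone
beads occupy type-independent positions in the helix frame, so an ideal
helix built by the fixture generators has exactly zero bond strain. All
distance targets used anywhere in the package — pair-restraint windows,
canonical-pair detection, bond lengths, stacking — are *measured* from these
templates, making geometry, restraints and detection mutually consistent by
construction. The targets can be replaced wholesale from a YAML config
(`read_energy_config()`) if a user prefers, e.g., distances measured from
crystal structures.

## The surrogate energy model

The original statistical potentials of the method family this package
follows are not published alongside it; `rnacg` therefore ships its own
transparent surrogate with the same interface, so that restraints, sampling
and analysis are fully exercisable. Every term and constant is a documented
argument of `energy_model()`:

* **Bonds** — harmonic terms `k (d - d0)^2` (`bond_k = 20` per Å²) over the
  intra-residue bead tree and the C4'(i)–P(i+1) backbone link, with targets
  measured from the ideal templates.
* **Excluded volume** — soft quadratic repulsion below `ev_radius = 3 Å`
  (`ev_k = 10`), skipping sequence-adjacent residues.
* **Pairing** — for every complementary candidate pair (AU, GC, GU;
  separation ≥ 3 within a chain) the summed deviation `dev` of the three
  base-bead distances from the cis-WW targets is scored with a Gaussian well
  `-pair_w exp(-(dev / pair_scale)^2)` (`pair_w = 3`, `pair_scale = 2 Å`).
  Wells are granted over a greedy one-partner-per-residue matching, so a
  residue cannot collect pairing energy from several partners at once — an
  exclusivity constraint without which sheared, collapsed states that touch
  many near-pairs outcompete genuine helices.
* **Helix cooperativity** — `-coop_w` (default 1.5) for each pair of
  adjacent matched rungs (i, j) and (i+1, j−1). This zipper term makes
  contiguous stems more favourable than the same number of scattered pairs;
  without it, simulations under soft restraints for two alternative
  structures stall in mixtures that satisfy two or three wells of each
  register.
* **Guidance** — a weak long-range pull `-guide_w / (1 + (d/guide_scale)^2)`
  between complementary glycosidic beads (`guide_w = 0.2`,
  `guide_scale = 8 Å`), giving unrestrained folding a gradient toward
  pairing contacts at distances the Gaussian well cannot see.
* **Stacking** — a Lorentzian well on consecutive glycosidic-bead distances
  centred at the ideal-helix value.
* **Restraint terms** — slope penalties, well bonuses, Watson–Crick-edge
  exclusion penalties and the chemical-probing score, described below.

These constants were calibrated once, during development, so that the model
folds the package's own 20–23-nt fixtures from an unfolded strand within a
few times 10^5 Monte Carlo steps; they are not fitted to any external data
and make no claim of thermodynamic realism. The energy is reported per term,
and the terms sum exactly to the total.

## Restraints

**Hard vs soft.** A base-pair restraint compiles to three atom–atom distance
restraints (glycosidic N–N, C2–C2, C6|C4–C6|C4) whose windows bracket the
family's template distances by ± `tol` (default 0.5 Å). In hard mode each
distance is a slope penalty — zero inside the window, `weight` per Å outside
— which strictly enforces a single structure; restraining one residue to two
different partners in hard mode is refused, because the sampler would try to
satisfy both at once and produce a distorted structure. In soft mode each
distance is a well bonus — `-weight` inside the window, zero outside — so
alternative, mutually incompatible structures can all be rewarded and the
simulation can explore them.

**Noncanonical pairs** are read from
`chain;res;type;chain;res;type;EEo` records (e.g. `A;8;A;A;21;G;HSt`),
cross-checked against the sequence, and compiled through the same three-
distance mechanism using the requested family template. Any edge combination
with either orientation is constructible; the quadruplex-style G–G WH cis
family used by the fixtures is just one case.

**Exclusions.** An `x` in a dot-bracket line discourages the residue from
canonical pairing: each *detected* canonical pair involving an excluded
residue adds `excl_penalty` (default +2) to the energy. It is a bias, not a
hard wall.

**Chemical probing.** Reactivities in [0, 1] (clamped; `NA` = unassigned)
enter as the squared error between the current pairing pattern (0 = paired,
1 = unpaired, from geometric detection at every energy evaluation) and the
profile, weighted by `probe_w` (default 1 per residue). Unassigned residues
are skipped. The pairing flags come from the same geometric detection used
everywhere, which is pseudoknot-capable; a nested-only variant of the flags
was considered and rejected as a second code path with no consumer in the
package.

## Sampling

Moves are (i) single-bead jitter (Gaussian, σ = 0.3 Å), (ii) rigid shifts
of one residue (σ = 0.6 Å) and (iii) pivot rotations of the chain segment
on one side of a randomly chosen backbone bead about a random axis
(σ = 0.35 rad). Because the energy is invariant under rigid motion, the
pivot always rotates the shorter side — equivalent to rotating the longer
side, and cheaper. Frozen residues are never displaced; pivot proposals
whose segment would sweep a frozen residue degenerate to the identity but
still count as attempted steps. All moves are symmetric and exactly
invertible, and acceptance follows the standard Metropolis rule
`dE <= 0 || u < exp(-dE / T)`.

Fixed-temperature runs (`run_mc()`, `run_unfold()`), geometric or linear
simulated annealing (`anneal()`), and replica exchange (`run_remc()`) share
the engine. Replica swaps between neighbouring temperatures are attempted
every `swap_every` steps (default 100 sweeps) with probability
`min(1, exp((1/T_i - 1/T_j)(E_i - E_j)))`, and exchange conformations — each
replica id keeps its temperature, so per-replica traces are directly
comparable. Frames are recorded every `frame_every` *attempted* steps; all
randomness flows through R's RNG, so a seed fully determines every output,
and `n_runs` repeats use seeds `seed + run - 1`.

Trajectories are plain text: a `key = value` header (sequence, chains,
residue numbering, bead names, field list, replica count, seed, run
parameters) terminated by a blank line, then one whitespace-delimited record
per frame with 17-significant-digit numbers, so write → read → write is
byte-identical. The header makes a trajectory self-describing: analyses can
be re-run later, with different parameters, from the file alone.

## Trajectory analysis

Analysis starts from the best-scored fraction of frames (lowest total
energy; default 1%, prominent as a parameter because it is a user choice,
not a constant), builds an all-against-all RMSD matrix — Kabsch
superposition by default, or raw coordinate RMSD for frozen-core runs where
superposition would hide the mobile-region signal — and clusters it with one
of three strategies, each returning at most five clusters:

* **Option D** (neighbour count): the frame with the most neighbours within
  the threshold becomes a representative, its neighbourhood the cluster;
  repeat on the remainder.
* **Option C** (quality threshold): grow candidate clusters under the
  complete-diameter constraint (all intra-cluster RMSD < threshold), extract
  the largest, recurse; the representative is the medoid. Exact maximum
  clique search is exponential, so growth is greedy by smallest diameter
  increase — on well-separated clusters this coincides with the exhaustive
  answer, which is how the tests validate it.
* **Option E** (best-energy seed): the best remaining frame seeds a cluster
  of everything within the threshold of it.

Ties anywhere resolve to lower energy, then the earlier (replica, step)
frame; option C breaks equal-size, equal-spread candidates toward the one
holding the best-ranked frame. The default threshold is 7 Å, a common
choice for ~50-nt RNAs; the package's own 20-23-nt demonstrations use 5–6 Å.
Model quality against a reference is measured with the base-pair Matthews
correlation coefficient over all i < j residue pairs, defined as 0 whenever
a contingency marginal vanishes (e.g. an unfolded prediction with no pairs).

## Synthetic data: what it does and does not show

The fixture generators produce ideal helices and hairpins (detection and
restraint-compilation oracles), extended coils, single strands (unfolded
starts), a 23-nt two-register sequence (`GCAGC AAAA GCUGC AAAA GCAGC`, whose
middle segment can pair with either flank — the alternative-structure,
riboswitch-like scenario), a quadruplex-like arrangement held by cyclic G–G
WH cis pairs, and synthetic reactivity profiles (paired residues near 0,
unpaired near 1, Gaussian noise, optional `NA` fraction) that emulate
SHAPE/DMS data after normalization.

These fixtures have known ground truth and idealized geometry. Passing the
package's property suite therefore demonstrates the *mechanics* — that hard
restraints enforce and soft restraints permit alternatives, that probing
restraints bias toward the planted structure, that clustering and RMSD obey
their definitions — on systems where the right answer is known. It does not
demonstrate predictive accuracy on real RNAs, which would require the
statistical potential and experimental reference structures that are outside
this package's scope. Synthetic reactivities in particular lack the
sequence-dependent noise, normalization artefacts and tertiary-contact
signals of real probing data.

## Problem sizes and numerical choices

The demonstration settings used by the quantitative checks were chosen as
the smallest systems that still show each behaviour: a 20-nt hairpin
annealed for 3×10^5 steps from 5 to 0.1 temperature units (hard-restraint
folding); the 23-nt two-register fixture sampled by replica exchange on a
five-temperature geometric ladder from 0.75 to 3.0 (three independent
1×10^5-step runs pooled per seed for the soft-restraint study; a
four-temperature ladder for the probing comparison); single-bead toys with
one harmonic bond for the Boltzmann-statistics and swap-rate checks
(10^5–10^6 steps). Detection tolerance is ±1 Å per base-bead distance;
restraint windows ±0.5 Å; energies are plain doubles with the term
breakdown kept consistent to 1e-9; degenerate inputs (empty restraint sets,
all-frozen conformations, empty trajectories) raise immediate errors rather
than propagating.

## Known limitations

* The surrogate potential is a development and demonstration vehicle: it
  folds short idealized fixtures, not arbitrary real RNAs, and its constants
  have no thermodynamic calibration.
* At these scales each replica-exchange run commits to a single fold: once a
  register of the two-register fixture zips, the run never melts and
  refolds into the alternative within 10^5–10^5.5 steps. Observing both
  alternatives therefore requires pooling several independent runs, and
  with roughly even register choice the chance that a small pool covers
  both remains material per seed. Much longer runs (or many more repeats)
  resolve this, at proportional cost.
* Because base-pair restraints are pure atom–atom distances (and distances
  are reflection-invariant), enforcing two mutually exclusive partners for
  the same residue in hard mode is geometrically satisfiable: the shared
  strand can bind one partner on its true face and the second on the mirror
  face, a triplex-like compromise rather than the distorted misfold strict
  enforcement might suggest. Orientation-aware restraints would forbid
  this; the three-distance translation keeps to the established format.
* Option C clustering is greedy; pathological tie structures could deviate
  from the exhaustive quality-threshold optimum.
* mmCIF support covers the `_atom_site` coordinate loop only.
* The move set has no loop-closure (crankshaft) move, so very long chains
  with both ends pinned would relax slowly.
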