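---
title: "Assessing proton half-channel integrity from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing proton half-channel integrity from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halfchannel)
```

## The problem

The membrane-embedded F~o~ factor of bacterial F~1~F~o~-ATP synthase moves
protons through two half-channels in its *a*-subunit.  In *E. coli*, the
inlet (periplasmic) half-channel narrows to a bottleneck near the
protonatable *c*D61 of the *c*-ring, lined by a chain of conserved polar
residues — *a*E219, *a*D119, *a*H245, *a*N214, *a*Q252 — and threaded by
structural water molecules that gather in recurrent cluster localizations
(W1 near *c*D61; W2/W3 between *a*H245 and *a*N214).  A proton can plausibly
hop between two polar heavy atoms when they sit within about 3 Å of each
other, the approximate length of a hydrogen bond.  Whether a continuous
chain of such contacts links the aqueous cavity to *c*D61 — and how point
mutations of the chain residues disturb the hydration that sustains it — is
the question this package operationalizes for molecular-dynamics
trajectories.  The proton itself is never simulated; the package analyzes
geometry, not quantum chemistry.

`halfchannel` provides the full analysis stack as composable functions: I/O
for multi-model PDB and CHARMM DCD trajectories, a conformational-stability
battery, water-cluster statistics, the hydrogen-bond chain graph and its
preserved/interrupted verdict, side-chain spatial-state classification,
gate-contact statistics, membrane-composition bookkeeping, and a synthetic
toy-system generator with exact ground truth.

## The chain model

Per frame, a graph is built whose nodes are the polar side-chain heavy
atoms of the chain residues (donor, acceptor, or both, from a fixed
residue/atom lookup) plus the water oxygens inside the analysis zone (the
union of the cluster-region spheres and a 6 Å corridor around the polar
chain atoms).  An edge joins two nodes when their distance is at most the
hydrogen-bond cutoff (3.0 Å by default) *and* one side is donor-capable
while the other is acceptor-capable; water oxygens count as both.  The
criterion is deliberately heavy-atom-only — hydrogens are rarely reliable
in the relevant force-field output, and the 3 Å heavy-atom distance is the
stated chain criterion — but a D–H···A angle filter can be switched on via
`hbond_criteria()` where hydrogens exist.

A frame is *connected* when any path joins a source atom (by default the
gate carboxylates of *a*E219/*a*D119) to a sink atom (the *c*D61
carboxylate).  `connectivity_fraction()` aggregates per-frame connectivity
into a percentage; a scenario is called **interrupted** when fewer than 5%
of frames are connected.  The narrative the verdict mirrors is binary and
never states a numeric cutoff, so the threshold is an explicit,
configurable operationalization: a chain that assembles in fewer than one
frame in twenty is not a usable proton pathway.  The same 5% default
operationalizes cluster "disappearance" (`cluster_absent` flags in
comparisons).  On our fixtures the two regimes are far apart — preserved
scenarios connect in well over half the frames, interrupted ones in none —
so the conclusions are insensitive to the threshold over a wide range.

Because a single frame-wise path is a strict reading, `connectivity_fraction()`
also reports segment-wise diagnostics: `broken_links` lists the adjacent
elements of the canonical chain (aE219 → aD119 → aH245 → W2/W3 → aN214 →
W1 → cD61) that never came within the cutoff in *any* frame.  Link
bridging is assessed by proximity alone (no donor/acceptor chemistry), so
it answers the coarser question "did these neighbors ever meet?", while
the per-frame verdict applies the full chemistry-aware path search.
Witness paths use hop-count-shortest routes; igraph's deterministic
traversal order makes reruns reproducible.

## Water-cluster statistics

A cluster region is a sphere (default radius 3.5 Å) centered at the
midpoint of two anchor-group centroids, recomputed every frame so the
region follows residue motion.  The anchors default to the CA atoms of the
residues that verbally localize each cluster (W1 between *a*N214 and
*c*D61, W2/W3 between *a*H245 and *a*N214); the geometry is configurable
because the source localizations are verbal, not metric.  W2 and W3 are
scored as one joint region by default, matching how they are reported;
separate regions are supported, and waters inside overlapping regions
count in each.

For a region, `cluster_stats()` returns the per-frame water count series,
the **occupancy** (percent of frames with at least one water — the plain
reading of "water observed in the localization"), and the **capacity
distribution** (relative frequency of each integer count over *all*
frames, zeros included).  Keeping zeros in the distribution makes the two
summaries mutually consistent by construction:
`occupancy_pct == 100 * (1 - capacity_pdf["0"])`, exactly.  Occupancy is
stored at full precision and displayed to 0.1%.  An alternative reading
would track per-molecule residence times; that is kinetics, out of scope
here.

## The stability battery

* **Superposition** is Kabsch via SVD with reflection correction; the
  returned rotation is always proper.  Tests verify it against an
  independent quaternion-method oracle to 10^-8^ Å.
* **RMSD series** fit each frame to the first frame over the selection
  (the reference is configurable; the source data do not state theirs, and
  no equilibration window is excluded by default).
* **RMSF** superposes frames to the time-mean structure, iterating the
  fit-to-mean pass to a 10^-12^ Å fixed point so the profile is
  independent of frame order and of which frame seeded the first pass;
  per-residue values are RMS over the residue's selected atoms.  The
  backbone set is N, CA, C, O.
* **Radius of gyration** is the mass-weighted RMS distance from the center
  of mass (standard atomic masses bundled; unit masses give geometric RG).
* **SASA** is Shrake–Rupley: probe 1.4 Å, 960 mesh points per atom by
  default, van der Waals radii from a bundled element table (H 1.20,
  C 1.70, N 1.55, O 1.52, S/P 1.80 Å).  The deterministic golden-spiral
  mesh is anchored to the system's principal axes, which makes the value
  exactly invariant under global rotation/translation — a property a
  space-fixed mesh only has up to quadrature error.  Mesh points that fall
  exactly on a neighbor's inflated sphere (possible only for degenerate
  coincident atoms) are credited to the lower-index atom, so a fully
  coincident pair contributes one sphere's area rather than zero or two.
  Doubling the mesh moves totals by well under 0.5% on fixture systems.
* **Intramolecular hydrogen bonds** count donor/acceptor heavy-atom pairs
  within the cutoff, excluding same-residue pairs and water, with the same
  chemistry rule as the chain graph.

`summarize_stability_table()` aggregates per-system rows (mean/min/max,
overall and mutants-only) with half-up rounding at the printed precision —
R's own `round()` is banker's rounding and would turn 1.5877 Å into 1.59
but 59.6 bonds into an unstable display elsewhere.

## Side-chain spatial states and gate contacts

`classify_sp()` featurizes a side chain as the per-frame centroid of its
terminal polar atoms after superposing each frame on the *local* backbone
(the residue ± 4 neighbors present on the same chain), which separates
side-chain repositioning from helix drift — important because two of the
mutants show appreciable helix displacement.  Positions are clustered by
k-means; k ≤ 3 is chosen by average silhouette width, falling back to a
single state when no split reaches a silhouette of 0.5 (silhouette is
undefined at k = 1, so the fallback rule is needed; 0.5 is the usual
"reasonable structure" reading of the index).  Frames farther than twice
the within-state RMS spread from every center are left unassigned; state
occupancies plus the unassigned share total 100%.  States are numbered by
first appearance, which keeps labels stable across reruns.  Where the
source distinguishes orientation ("towards aH245" vs "towards cD61"),
users can label recovered centers by their nearest reference group; the
package reports geometry and leaves that naming to the caller.

`contact_fraction()` uses a strict inequality (distance *less than* the
cutoff), matching the wording "at a distance of less than 3 Å"; a frame
sitting exactly at the cutoff is not a contact.  `ca_distance_pdf()` bins
per-frame CA–CA distances at 0.2 Å by default (the figures it mirrors
state no binning) and returns a density that integrates to one.

## Membrane bookkeeping

`class_percentages()` reduces a lipid species table to class shares with
half-up integer rounding plus largest-remainder reconciliation, so shares
always total 100.  The bundled `reference_membrane()` (206 DYPE + 96 DPPE
+ 96 PMPE phosphatidylethanolamines, 108 PMCL + 36 TYCL dianionic
cardiolipins) reduces to 73% PE / 27% CL from exact shares 73.43/26.57.
`net_charge_check()` verifies electroneutrality: 144 CL^2−^ lipids are
balanced by 288 K^+^ at zero protein charge.  This module validates
metadata only; no coordinates are built.

## The synthetic generator, and what passing tests mean

Trajectory-dependent published values (occupancies of 92%/44%/36%, mean
inter-residue distances, absolute RMSD/RG/SASA) cannot be recomputed
without the original 150 ns trajectories, which are not distributed.  The
package therefore ships a generator whose outputs have *known* ground
truth, so that every estimator can be validated exactly, and whose
per-mutant fixtures encode the published qualitative outcomes as study
conditions.

The toy half-channel places the chain sites on a line: gate spacings of
2.7 Å are direct contacts; the two 5.0 Å gaps flanking the water regions
are bridged exactly when a water is present, because waters are placed
uniformly within 0.5 Å of the region center and 2.5 + 0.5 = 3.0 Å.  An
always-present "gate water" between *a*D119 and *a*H245 models the hydrated
aqueous-cavity exit (and lets carboxylate-only gates connect onward, since
two acceptors cannot bond directly); its 0.3 Å placement radius keeps it
at least 3.05 Å from any W2/W3 water, so it can never bypass the *a*H245
relay.  Waters scheduled absent are parked in a distant reservoir so the
atom count is constant across frames, as in real MD output.  Per-frame
counts follow a presence/capacity model: zero with probability 1 − p,
otherwise a draw from the capacity distribution restricted to counts ≥ 1.
Backbone atoms get 0.05 Å Gaussian jitter, side chains 0.08 Å around
their current spatial mode; one RNG stream per trajectory keyed by the
seed makes fixtures bit-reproducible.

Ground-truth connectivity is computed by an exhaustive depth-first search
written independently of the analyzer's igraph-based machinery, using the
same 3 Å criterion — deliberate oracle duplication, not shared code.

The ten fixtures set W1 presence to the published occupancies where stated
(0.92 WT, 0.44 aH245G, 0.36 aN214L), zero W2/W3 presence for aH245G and
zero W1 presence for aH245Y (the reported cluster disappearances),
capacity support of at most 2 for the wild-type W2/W3 and up to 4 for
aQ252L, and qualitative elevations (revertant, aH245S) or reductions
(aE219G/Q on W1, aN214H on W1 capacity) where only direction is reported;
the unreported magnitudes were chosen once at plausible values and are not
tuned.  In the fixtures the *a*N214 side chain keeps a single spatial
mode: a multi-mode displacement of the 2 Å separation the spec of a
recoverable mode demands would itself break the 3 Å bridging geometry, so
multi-state SP recovery is exercised on dedicated toys whose tracked side
chain (*a*Q252) sits off the proton path.

What passing tests show — and do not show.  The generator reproduces the
*statistical* structure of half-channel hydration (presence/capacity
schedules, mode-switching side chains, jittered backbones, geometric
bridging), not water dynamics, electrostatics, membranes, or force-field
energies.  A green suite certifies that the estimators recover known
parameters and that the pipeline maps the encoded hydration patterns to
the published verdict matrix; it does not re-derive those patterns from
physics.

## Numerical choices and degenerate inputs

Distances compare with `<=` at region boundaries and hydrogen-bond cutoffs
(strict `<` only for contacts, per the source wording).  Superposition
refuses collinear or coincident selections.  PDB insertion codes are
rejected; alternate locations keep the highest-occupancy conformer with a
warning; recognized water residue names are HOH/TIP3/WAT/SOL
(configurable).  Residue numbers follow the file verbatim — the field
names residues by author numbering (aE219, cD61), so re-indexing would
only obscure.  PDB coordinates round-trip at the format's 3-decimal
precision, DCD at single precision.  Capacity distributions must sum to 1
within 10^-9^; occupancy/PDF consistency is exact by construction.

## Problem sizes

Default analyses use 150-frame fixtures of ~45 atoms; estimator-recovery
checks pool 5 seeds × 200 frames per grid point, oracle comparisons use 50
random instances, and the SP-recovery toys run 300 frames.  These sizes
give comfortable statistical margins (3-standard-error bands) while
keeping the whole suite fast enough to run habitually; all scale linearly
if enlarged.

## Known limitations

* Verdicts on real trajectories depend on the analysis-zone and region
  geometry defaults, which encode verbal localizations; sensitivity to the
  radius should be checked per system (`cluster_stats` makes this cheap).
* The heavy-atom bond criterion admits donor–acceptor pairs whose
  hydrogens point elsewhere; enabling the angle filter needs hydrogens.
* Occupancy is a frame-counting quantity; it does not distinguish one
  long-lived water from many transient ones.
* k-means SP states assume roughly isotropic, comparable-spread modes;
  strongly anisotropic rotamer clouds would need a different featurization.
* The DCD reader/writer pair covers the common little-endian CHARMM layout
  without unit-cell records.
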