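---
title: "Quantifying BAR-domain membrane binding and curvature generation with memBAR"
author: "memBAR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying BAR-domain membrane binding and curvature generation with memBAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memBAR)
```

# The scientific problem

BAR (Bin/Amphiphysin/Rvs) domains dimerise into banana-shaped α-helical
modules whose concave face carries clusters of basic residues.  When such a
dimer docks onto an anionic bilayer — for instance a membrane with a
mitochondrial-inner-membrane-like composition rich in PI(4,5)P₂ and
cardiolipin — three things happen that one wants to quantify from
simulation and structural data:

1. *which residues hold the membrane*, and how persistently;
2. *what the membrane does in response* — how lipids redistribute around
   the protein and how the bound leaflet bends;
3. *what the protein does in response* — how the dimer's concave angle
   relaxes as it engages the bilayer.

memBAR implements the corresponding estimators, together with the static
crystallographic geometry of the dimer (helix angles, extent, buried
interface) and a seeded synthetic-data generator that makes every stage
testable against known ground truth at desk scale.

# Data model and units

All coordinates are stored in nanometres and times in picoseconds,
whatever the source format (PDB files are converted from Ångström on
reading); areas are reported in Å² because crystallographic interface
areas are conventionally printed that way.  The z axis is the membrane
normal; x is the membrane long axis.  A `Structure` is an ordered atom
table with chain/residue identity; a `Trajectory` is a time-ordered,
uniformly spaced sequence of coordinate frames over a fixed topology with
orthorhombic periodic boxes.  Triclinic boxes are refused explicitly: the
analyses are defined on rectangular boxes, and silently mishandling a
skewed box would be worse than an error.

Trajectories travel in a plain-text *frame table* (CSV: `frame`,
`time_ps`, `box_x/y/z`, then `x0,y0,z0,x1,...` in topology order) written
by a deterministic formatter, so identical runs produce byte-identical
files.  Any binary-trajectory reader can be substituted as long as it
produces the same `Trajectory` contract.  One format caveat is worth
knowing: GRO files carry no chain identifiers, so a topology that must
distinguish the two protomer chains (the concave-angle analysis, interface
geometry) should travel as PDB; the generator's `simulate` subcommand
writes both.

# Residue–lipid contacts and the occupancy statistic

A residue is *in contact* with a lipid class in a frame when the minimum
heavy-atom distance between the residue and any lipid of that class,
under the minimum-image convention, is at most the cutoff (default
0.4 nm).  Distance criteria of this kind are sometimes phrased ambiguously
("at least 0.4 nm"), which taken literally would define interaction by
*separation*; the package adopts the standard reading — interaction when
the minimum distance is *within* the cutoff — and exposes the cutoff as a
parameter.

Occupancy of a residue is the longest continuous contact period divided by
the simulation time elapsed after the first contact between *any* protein
residue and *any* membrane phospholipid (all five classes jointly, not the
queried class only):

$$\mathrm{occ}(r) \;=\; \frac{k(r)\,\Delta t}{T_{\mathrm{total}} - t_{\mathrm{first}}},$$

clipped to [0, 1], where $k(r)$ is the longest run of consecutive contact
frames.  A run of $k$ frames counts as $k\,\Delta t$ — each frame
represents one sampling interval — so a residue in contact at every frame
from the first global contact onward scores exactly 1.  The alternative
$(k{-}1)\,\Delta t$ convention (elapsed time between the run's endpoints)
is available as a flag.  Occupancy is dimensionless and invariant under
uniform time rescaling.  Per-residue profiles are computed per lipid class
and can be pooled over all phospholipids (`lipidClass = "ALL"`); replicate
aggregation reports element-wise mean and sample SD (n − 1).

Contact detection uses an exact cell-grid neighbour search (cell edge at
least one cutoff, capped at 64 cells per dimension) that falls back to the
exhaustive scan for small or aperiodic boxes; the test-suite asserts exact
agreement with the O(N²) oracle on random instances.

# Membrane fields

*Leaflet assignment* defaults to the sign of a marker's z against the
instantaneous mean marker z; a local-midplane variant (mean z within a
lateral neighbourhood, default radius 3 nm) is available for strongly
deformed membranes, where the global midplane misassigns lipids — the test
suite quantifies this on a tilted synthetic bilayer.  The marker of every
phospholipid is its phosphorus atom; cardiolipin carries two phosphates
and uses their midpoint throughout.

*2D density maps* bin marker xy positions per frame, average counts over a
trailing window (default the last 100 ns, truncated to the trajectory
span) and divide by bin area (default 0.2 nm bins), giving lipids/nm².
For a diffusing monomer the map defaults to protein-aligned frames —
recentred on the protein's centre of geometry and rotated in-plane so its
first principal axis lies along x — because a lab-frame map of a mobile
protein smears the lipid structure around it.  The alignment is recorded
in the output metadata.  The integral of the map over the mapped region
equals the mean per-frame lipid count (conservation is asserted to 1% in
the tests; the residual comes only from edge effects).

*Height profiles* bin the selected leaflet's marker z along x (default
1 nm bins, sampled every 200 ps; the stride must be an integer multiple of
the frame spacing).  Bins that never receive a marker are flagged missing
and never interpolated.  Replicates aggregate to per-bin mean ± sample SD.
The profile of binned phosphate heights is the primary output;
*curvature* is an explicitly derived estimate on top of it,
$\kappa(x) = -z''/(1+z'^2)^{3/2}$ by central differences on the binned
means, with the sign convention that a bulge toward the protein side (+z)
is positive.  Ends and neighbours of missing bins are NA; at least five
consecutive non-missing bins are required.  On a sampled circle arc of
radius 10 nm with 1 nm bins the estimate is within 0.3% of 1/R.

The default profile restricts to one leaflet (the bound, upper leaflet)
rather than pooling all phospholipids of the bilayer; both selections are
supported (`leaflet = "both"`), since either choice is defensible when the
quantity of interest is the bend of the bound face.

# Dimer conformation

The concave angle is measured at the Cα centroid of a central residue
group, subtended by two arm-tip residue-group centroids.  There is no
standard residue triplet for this angle, so the package default is a
documented, configurable choice: arm tips =
residues 132–136 of each chain (the distal-arm membrane-binding cluster
Arg132/Arg134/Arg136) and centre = residues 2–10 of both chains at the
six-helix-bundle core.  The groups are fully configurable and are recorded
in the pipeline outputs.  No smoothing is applied by default; an optional
centered moving average records its window.

# Static structure geometry

Helix axes are the dominant principal direction of the Cα cloud of a
residue range (≥ 10 Cα required; gaps from disordered residues are
tolerated), oriented from low to high residue number.  The inter-helix
angle is reported with the acute convention arccos|â₁·â₂| — consistent
with how BAR-domain curvatures are conventionally quoted — with the
signed variant behind a flag.  Dimer length is the Cα extent along the
first principal axis; the bundle diameter is defined here as twice the RMS
radial Cα distance within the central 20% of that length (a package
definition, documented because reported bundle diameters are typically
qualitative).

SASA uses Shrake–Rupley with a deterministic Fibonacci lattice (default
960 points, probe 1.4 Å) over a pinned Bondi-type van der Waals radius
table (`vdwRadii()`; unknown elements are an error, and the table is a
configurable argument so it can be swapped without code changes).
Isolated-sphere accuracy at 960 points is well within 0.5%, and the
two-sphere case is tested against the closed-form spherical-cap solution.
One numerical choice deserves emphasis: the quadrature lattice is
expressed in a canonical frame derived from the structure's own coordinate
covariance (eigenvectors, signs fixed by the first atom with a
non-negligible projection, right-handed).  Because the frame co-rotates
with the molecule, SASA — and everything built on it — is invariant under
rigid rotation and translation of the input to ~1e-6 relative, rather
than only to quadrature error.  Structures with exactly degenerate
principal moments (an ideal sphere) have no canonical frame and only
translation invariance.

Buried interface area follows the PISA convention,
ΔA = (SASA_A + SASA_B − SASA_AB)/2, which is what structure-deposition
interface servers report per complex; the summed buried area of both
chains (2ΔA) is also exposed because published totals are sometimes quoted
that way.  Interface residues are those with positive ΔSASA; the
hydrophobic census counts residues from the documented set {Ala, Val,
Leu, Ile, Pro, Phe, Met, Trp} with buried fraction above a threshold
(default 0.70).  Interface hydrogen bonds use heavy-atom donor–acceptor
distances only (default ≤ 3.5 Å) over a bundled typing table — a 2 Å
crystal structure has no hydrogens, and server-side criteria are not
published, so the bond count is treated as a soft reference rather than a
hard target.

# The synthetic-data generator

The generator emulates the study conditions of the simulated systems: a
monomer placed 3.4 nm above a bilayer in an 18 nm cubic box, or a dimer
placed 0.2 nm above a 45 × 15 × 15 nm bilayer; frames every 200 ps; three
replicates; lipid composition POPC:POPE:POPS:PI(4,5)P₂:cardiolipin =
40:32:3:5:18, a mitochondrial-inner-membrane-like liposome recipe with its
2% fluorescent tracer dropped and the remainder renormalised.  The exact
composition tables of the full simulated membranes are not reproduced
here, so this ratio is a clearly labelled stand-in.  Class counts per leaflet
are apportioned by largest remainder; 0.65 nm² per lipid is a
literature-typical area that affects only fixture realism.  Default run
length is 100 frames (20 ns-equivalent at the 200 ps stride): long enough
for the statistical checks (about 2,300 marker samples per 1 nm bin on the
large box), small enough that the full suite runs in minutes on one CPU.

Lipids are 3-point pseudo-molecules (marker P plus two dressing carbons;
cardiolipin: two P atoms plus one carbon) — the analyses only consume
marker positions and heavy-atom distances, so atomistic lipid geometry
would add cost without adding testable signal.  Leaflet z is
midplane ± half-thickness (5 ± 2 nm) plus a prescribed height field
(flat, Gaussian bump, or sinusoid) plus Gaussian thermal noise truncated
at 3σ.  The truncation keeps the scripted distance guarantees
deterministic; it shrinks the effective SD by ~1.4%, which the
SE-based tests absorb.

The synthetic dimer is two pseudo-atomic Cα traces related by a two-fold
axis: an antiparallel core along x (the six-helix-bundle stand-in, chains
offset 0.1 nm) and distal arms rising at half the inter-arm angle, with
residues numbered from 2 so the standard selections resolve and the
membrane-binding clusters carry their true identities.  Requested
inter-arm angle and end-to-end length round-trip exactly through the
geometry estimators.  This object reproduces prescribed *geometry*, not an
atomistic packing interface: its buried area and hydrogen-bond census are
internally consistent but not comparable to crystallographic values, which
is why files and docs label it synthetic.

Scripted trajectories realise three kinds of ground truth exactly:

* *contact schedules* — the scheduled residue is protruded to 0.3 nm above
  its designated lipid's marker during its window and rests with the
  protein otherwise; scheduled residues and designated lipids are exempt
  from noise so the within-0.35 nm / beyond-0.6 nm guarantees hold
  deterministically.  A schedule therefore requires protein clearance of
  at least 0.6 + 3σ + 0.2 nm above the bilayer (the generator validates
  this), which the 3.4 nm monomer offset satisfies;
* *concave-angle ramps* — rigid in-plane arm rotations about the core
  hinge; because hinge and both tip centroids lie in one plane, the
  measured angle equals the target exactly at every frame in the
  noise-free case;
* *height fields* — marker home positions record the analytic field, so
  profile tests compare against the exact per-bin expectation rather than
  a bin-centre approximation.

Reproducibility: R's Mersenne-Twister generator, seeded per replicate with
`seed + 7919·replicate`; a spec and seed always regenerate bit-identical
output, and generated GRO/frame-table files re-read through the package
reproduce generator coordinates to 1e-4 nm (the formats' printed
precision: GRO is written at 5 decimals, frame tables at 10 significant
digits).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: lipid internal structure and packing, water and
ions, protein secondary structure and side chains, realistic diffusion
(lipids vibrate about home positions rather than diffusing), membrane
undulation spectra, and any force-field physics.  The tests establish that
the estimators are correct; they say nothing about sampling adequacy of a
real trajectory.

# Pipeline and reproducibility of outputs

`runPipeline()` takes a YAML (or list) configuration naming the topology,
replicate frame tables and enabled analyses, validates the schema (unknown
keys are an error naming the offender), and writes plain CSV tables with
JSON sidecars plus a manifest recording the configuration verbatim, input
MD5 checksums and the package version.  Every sidecar carries the manifest
MD5, outputs contain no timestamps, and re-running an identical
configuration is byte-identical — asserted in the tests.  Exit codes of
the command-line wrapper: 0 success, 2 configuration error, 3 data error.

# Known limitations

* Orthorhombic boxes and first-model PDB only; insertion codes rejected.
* The crystal-structure acceptance comparisons need the deposited entry
  (8CEG) supplied locally; it is not redistributable with the package.
* Curvature is a 1D estimate along x; no 2D curvature tensor or Helfrich
  fitting.
* The hydrogen-bond criterion is distance-only by design (no hydrogens in
  the intended inputs); counts are softer than geometric areas.
* The density-map alignment protocol is a reasonable default
  (centre + first principal axis), not a reconstruction of any particular
  published plotting script.
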