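---
title: "Methods: quantifying CLC antiporter mechanism data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying CLC antiporter mechanism data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clcdyn)
```

CLC transporters exchange two chloride ions for one proton. The evidence
for how they do it comes from four very different kinds of data — MD
trajectories, cryo-EM density maps, HDX-MS uptake tables, and
proteoliposome flux traces — and this package implements the quantitative
step for each. This vignette explains the models behind those steps, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not establish.

## Conventions

All coordinates are in Ångström. The membrane normal is the z axis and the
extracellular side is at +z; a `membrane_frame(z_inner, z_outer)` fixes the
leaflet planes. Waters are recognized by residue name (HOH/WAT/TIP3/SOL by
default, extensible), ions and lipids likewise. Distances are
minimum-image when a trajectory carries an orthorhombic box; trajectories
are expected pre-imaged and protein-centered, as produced by standard
re-imaging tools. Frames default to 0.2 ns spacing, the production save
interval this analysis is designed around.

## Hydrogen-bond graphs and water wires

A water wire is a chain of hydrogen-bonded waters; such chains are the
minimal structural requirement for Grotthuss-style proton hopping through
a hydrophobic protein interior. We build a per-frame geometric H-bond
graph over water oxygens plus designated protein endpoint atoms (e.g. the
gating-glutamate carboxylate oxygens). The criteria are the field's
standard water geometry — donor–acceptor heavy-atom distance ≤ 3.5 Å and
D–H···A angle ≥ 150° — because no single H-bond definition is canonical;
both numbers are config keys (`hbond_criteria()`), and wire statistics
should always be reported alongside the criteria used. Either partner may
donate; endpoint heavy atoms without attached hydrogens act as acceptors.
A distance-only mode exists and is, by construction, a superset of the
angular mode at equal cutoff. Candidate pairs come from a cell-list grid;
the test suite holds the grid path equal to an all-pairs evaluation on
randomized frames, so the acceleration is behaviorally invisible.

Wire search is a breadth-first (fewest-hop) walk from each source atom to
the sink set. Intermediate nodes are water oxygens only: protein side
chains may be endpoints but not relays (a switch exists, off by default,
because wires bordered by — rather than passing through — the intracellular
glutamate are the reported phenomenon). The sink, "bulk intracellular
solvent", is operationalized as water oxygens below the inner leaflet
plane. Where several shortest paths exist, the smallest-atom-id sink and
smallest-id predecessors are chosen, making the reported wire
deterministic. Every reported wire re-validates edge-by-edge against its
frame's graph.

Wires are sorted into three classes by route: class 1 reaches the anion
permeation pathway, classes 2 and 3 reach the gating glutamate in its
"out" rotamer through two different linings. Only class 1's source
constraint is structurally unambiguous; the class 2 / class 3 distinction
is depicted rather than defined in the structural literature, so the
shipped shells (the proton-pathway glutamates for class 2, an adjacent
interface shell for class 3) are an interpretive default, flagged as such,
and fully configurable (`wire_class_def()`). Classification is by maximum
wire-water/shell contacts within 4 Å, ties to the lowest class id,
`"unclassified"` when no shell is touched.

Abundance is quantified per simulation as the fraction of frames with at
least one wire of any class, then summarized across simulations with
median, linear-interpolation quartiles (R type 7 — the convention had to
be picked and is stated here), and whiskers at the last data points within
1.5 × IQR; points beyond are listed as outliers.

## Ion unbinding and gate opening

Chloride occupancy of the anion pathway is tracked as the per-frame
minimum distance from the inner-gate tyrosine's hydroxyl oxygen (residue
445; the reference set is configurable) to the nearest Cl⁻. The trace is
smoothed with a centered moving average whose window is the nearest odd
frame count to 20 ns — 101 frames at 0.2 ns/frame — shrinking symmetrically
at the edges; a trailing-window mode exists for causal analyses. An
unbinding event is an upward crossing of the 12 Å threshold in the
smoothed trace (a raw-trace mode supports sensitivity checks); a run
"shows leaving" only when every pathway ion has an event and ends unbound.
Smoothing is applied before thresholding so single-frame excursions do not
count as events; the price is a timing uncertainty of up to half a window
(≈10 ns), which the tests budget for explicitly.

Exit direction is read only once the ion has committed: at the first frame
the ion is ≥ 15 Å from the pathway-site centroid (deliberately beyond the
12 Å unbound threshold), the sign of its displacement along the membrane
normal gives "extracellular" or "intracellular"; an ion that recrosses
before committing is "indeterminate". The unbound occupancy fraction is
the fraction of smoothed frames above threshold, and bound + unbound = 1
exactly. Inner-gate opening is the S107–Y445 side-chain oxygen separation;
the 6 Å open threshold is interpretive (no canonical value exists) and
configurable.

## Map z-scores

To compare an ion-site signal between maps with different absolute
intensity scales, the density at a coordinate is normalized by the whole
map: Z = (ρ − μ)/σ with μ and σ (population SD) over every voxel — no
solvent mask, though a masked mode exists. Values are trilinearly
interpolated (nearest-voxel mode for sensitivity checks); at grid nodes
interpolation equals direct lookup, which is tested. A constant map has
σ = 0 and z-scores on it are a hard error, not a number. The MRC/CCP4
reader follows the 2014 standard: mode-2 maps, axis order permuted from
MAPC/MAPR/MAPS onto x/y/z, origin from the ORIGIN record or NXSTART
fallback.

## Cα RMSD

Residue pairing is chain-aware: chains are matched greedily by alignment
overlap, sequences within matched chains are globally aligned
(Biostrings), and only identically-aligned residues pair — identical
sequences reduce to the identity pairing. Superposition is the Kabsch
least-squares fit on paired Cα atoms with the reflection guard (rotation
determinant +1, property-tested). Pruning is off for headline values
because iterative-pruning results depend on cutoffs that published
comparisons rarely state; a matchmaker-like 2 Å iterative prune is
available, and both all-pair and post-prune RMSDs are always reported so
no single number hides the choice.

## HDX-MS pH normalization

Backbone-amide exchange chemistry is pH-dependent, so uptake measured at
different pH values is not directly comparable. The intrinsic
(unprotected) rate is modeled with the standard three-term form

k_int(pH) = k_A·10^(−pH) + k_B·10^(pH − pKw) + k_W,

with sequence-averaged poly-DL-alanine reference constants near the
experimental temperature (21 °C), expressed per second. Per-residue
sequence corrections are out of scope: only rate *ratios* enter the
normalization, and those are far less sequence-sensitive than absolute
rates. In the base-dominated regime (pH ≳ 4.5) the rate falls ~tenfold
per pH unit; with these constants the pH 6.5 → 4.5 correction factor is
90.7, and the model has its minimum near pH 3.3, below which factors are
flagged "approximate" since the log-linear extrapolation breaks down
(`correction_factor()` carries the flag).

A matched time point multiplies exposure by the correction factor so that
k_int·t is equal: 20 s at pH 6.5 pairs with ≈1813 s at pH 4.5 under the
default constants. Differential uptake at matched exposures is then a
chemistry-free comparison: a positive difference at the lower pH means the
protein exchanges faster than its chemistry allows — enhanced solvent
accessibility, i.e. a conformational change. Matched times are aligned to
the measured grid by nearest timepoint within a factor of 1.5, else
log-time interpolation; timepoints whose matches fall outside the grid are
dropped and reported. Back-exchange correction scales by
max_exchangeable/FD-control, warns (and clips) when a corrected value
overshoots the theoretical maximum by more than 5%.

## Flux quantification

In the vesicle assay, transport is electrically silent until valinomycin
collapses the membrane potential, so rates are least-squares slopes over a
window (default 10 s) starting at valinomycin addition; a Theil–Sen option
guards against electrode spikes. Chloride slopes convert to mol/s through
the extravesicular volume; pH slopes additionally through a user-supplied
buffering capacity (mol H⁺/pH/L) — the package deliberately refuses to
guess this conversion, and likewise the transporter count is a required
input rather than a hidden assumption. Division by the transporter count
gives ions/s per transporter.

Two guards encode the assay's logic. First, under the imposed two-fold
outward H⁺ gradient any inward H⁺ movement must be active transport, so a
*negative* post-valinomycin proton slope is reported as leak, never as
transport. Second, a proton slope below twice its regression standard
error is below the detection floor and reported as zero — and a zero
proton rate makes the stoichiometry an explicit "uncoupled" NA, never a
number. Stoichiometry is aggregated as the mean of per-replicate ratios
with SEM, not the ratio of mean rates; the two differ on heterogeneous
replicates, and the ratio-of-means is additionally biased for noisy
denominators.

## What the synthetic generators do and do not show

Every stage has a seeded generator emitting fixtures in the same formats
the real pipeline reads (PDB/DCD topologies and frames, MRC maps, TSV
tables) plus a machine-readable ground-truth sidecar; identical arguments
give byte-identical files. The fixtures are geometric and statistical
stand-ins, not physics: wire fixtures plant an ideal 2.8-Å-spaced,
near-linear water chain (jitter σ 0.04 Å) with rejection-sampled decoys
kept a cutoff away; ion walks fluctuate (σ 0.5 Å) around a 5 Å anchor and
then drift out at 2 Å/ns; density blobs replace the local noise
realization so the planted peak is exactly μ + peak; uptake curves follow
the one- or two-population exponential model with Gaussian noise; flux
traces are piecewise-linear with electrode noise (2×10⁻⁴ mM Cl⁻, 10⁻⁴ pH
at 5 Hz — the scale at which programmed WT-like rates are recovered to a
fraction of a percent).

Passing tests on these fixtures therefore demonstrate that the estimators
recover known truth under idealized geometry and noise — correctness of
the computation, not of any biological claim. They say nothing about
force-field adequacy, sampling convergence, map reconstruction quality, or
peptide-level exchange chemistry in a real protein. Re-analysis of
deposited trajectories and maps is possible through the same readers but
requires downloads and is outside the tested surface.

## Problem sizes and seeds

The shipped tests and the acceptance script run at desk scale, chosen so
the statistical checks are meaningful while the whole suite stays fast:
2000-frame wire trajectories with ~55 waters for the binomial fraction
checks, ten 1.5-µs (7500-frame) ion walks per condition, 48³-voxel maps,
120-residue models, eight-timepoint uptake curves, and six flux
replicates. Every random step takes an explicit seed; the pipeline
(`run_pipeline()`) refuses configs without one and serializes the full
effective configuration next to its outputs.

## Known limitations

* Proton transport itself is not simulated and no excess proton is
  modeled; wires are a hydration-connectivity statistic only.
* The class 2 / class 3 wire distinction is an interpretive default.
* XTC trajectories are not read; convert to DCD or multi-model PDB.
* The intrinsic-rate model is sequence-averaged; per-residue k_int (and
  hence absolute protection factors for real peptides) is out of scope.
* Transporter counts and buffering capacities are user inputs;
  per-vesicle occupancy statistics are not modeled.
* Cl⁻ *entry* kinetics are not analyzed — binding-site diffusion is a
  longer-timescale process than unbinding and is not represented in the
  generators either.
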