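---
title: "Methods: how deamscan models AID substrate discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how deamscan models AID substrate discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deamscan)
```

## The scientific problem

Activation-induced cytidine deaminase (AID) deaminates cytosine (C) to
uracil in single-stranded DNA and 5-methylcytosine (5mC) directly to
thymine, but shows no detectable activity on 5-hydroxymethylcytosine
(5hmC). Point mutants decouple the two activities: the N51A substitution
abolishes C deamination while retaining robust 5mC activity. `deamscan`
implements the computational analyses by which this discrimination can be
dissected: catalytic-pocket geometry over molecular-dynamics (MD)
trajectories, substrate ring breadths against the pocket gate,
protein–DNA interaction fingerprints, conformational clustering for
model-vs-crystal comparison, an in-silico twin of the glycosylase-coupled
activity assays, and a sequence-context (NNCN) mutation-calling pipeline.
Every analysis runs on synthetic inputs produced by the package's own
generators, so the full chain is testable without external downloads.

## Pocket geometry and the steric argument

The catalytic pocket is sized by four heavy-atom distances: residue 51
(ND2 of asparagine, or CB in the N51A mutant) to Y114 CE2, to P86 CB and
to C87 SG, plus Y114 CE2 to H56 CE1 (the pocket height). The residue-51
to P86 distance (`d2`) is the *gate*: it bounds the breadth of a
heterocyclic ring that can enter. `pocket_distance_series()` measures all
four in every trajectory frame and reports the mean, minimum and maximum
per pair.

Substrate breadths come from idealized base geometries built at run time
from standard planar pyrimidine reference coordinates with
exocyclic substituents placed along external bisectors (C5–CH3/CH2 1.496,
C–H 1.08, N–H 1.01, CH2–OH 1.43 Å, tetrahedral angle at the
hydroxymethyl carbon). The *breadth* of a ring is defined here as its
lateral van-der-Waals span: the in-plane-projected distance between the
C2-carbonyl (O2) surface on one flank and the C5-substituent surface on
the other, including both atoms' Bondi radii and maximized over the atoms
of each flank. This is the widest cross-section that must pass the gate.
With this convention the package computes 7.80 Å for C, 8.72 Å for 5mC
(heavy-atom headline; the methyl-hydrogen-inclusive value is available
via `include_substituent_hydrogens = TRUE`), and a 9.0–9.2 Å range for
5hmC over a 10°-grid scan of the hydroxymethyl dihedral. A pure
perpendicular-axis projection was considered and rejected: it
understates the lateral extent of the carbonyl flank by about 0.7 Å and
does not reproduce the vdW-inclusive widths this convention yields.

`fit_assessment()` turns a breadth (or a rotamer range, whose maximum is
used) into a verdict against the gate's minimum and mean. The hydration
argument is encoded as two documented constants on the radius table —
`water_bulk_min = 2.8` and `water_bulk_max = 3.2` Å, the steric bulk one
bound water molecule adds to a hydroxyl group. Adding even the lower
bound to the 5hmC breadth pushes it past the gate minimum, which is the
package's formalization of why hydrated 5hmC cannot enter the pocket. No
solvation energetics are modeled; the constants are the whole argument.

## Interaction fingerprints

Three detectors classify protein–substrate contacts per frame:

* **Hydrogen bonds**: donor–acceptor heavy-atom distance ≤ 3.5 Å and,
  when the donor carries hydrogens (found geometrically within 1.25 Å),
  best D–H…A angle ≥ 120°; hydrogen-free donors are judged on distance
  alone. Donors are N/O/S, acceptors N/O.
* **vdW contacts**: heavy-atom pairs within the Bondi radius sum + 0.6 Å,
  excluding pairs already classified as hydrogen bonds in the same frame
  (the classifications are exclusive, so the two counts are disjoint).
* **π-stacking**: ring pairs with centroid distance ≤ 4.5 Å, best-fit
  plane angle ≤ 30° (folded to [0°, 90°]) and lateral offset ≤ 2.0 Å.

No consensus criteria exist for these cutoffs; the defaults are the
community-standard values and every one is configurable through
`interaction_config()` and echoed into output provenance. The analyses
that matter here are *planted-fixture* analyses — the tests verify that
the detectors agree exactly with brute-force all-pairs oracles and that
constructed complexes reproduce the qualitative signatures (loss of the
N51–O2 hydrogen bond in N51A complexes; gain of the methyl bridges to
W84 and T27 upon methylation) — so conclusions do not hinge on the
absolute cutoff values.

`aggregate_network()` collapses per-frame detections into one record per
(kind, partner pair) with a frame occupancy and a mean distance over
present frames; an interaction "exists" at occupancy ≥ 0.5 and a stack is
"stable" at ≥ 0.7 (both configurable). Contacts from any 5mC methyl atom
collapse onto a single `5mC-methyl` partner so that network diffs narrate
the methyl bridge as one partner. `triple_stack_series()` tracks the
W84:Y114:G stack and its A:Y114:G alternative frame by frame.

## Conformational clustering

`pairwise_rmsd_matrix()` computes superposition-optimal RMSDs (Kabsch via
SVD; C-alpha by default) between all frame pairs. `kelley_cluster()`
builds an average-linkage hierarchy and selects the cluster count by the
Kelley penalty: the average within-cluster spread at each level, min-max
normalized onto [1, n−1] across hierarchy levels, plus the cluster count,
minimized over k = 2..n−1 with ties toward smaller k. Two numerical
choices matter and are deliberate:

* the one-cluster level participates in the normalization as its anchor —
  without it, every candidate level of a well-separated two-cluster
  trajectory has an equally tiny spread and the rescaling amplifies
  noise, so k = 2 would never be selected;
* a spread floor (`flat_tol = 1e-3` Å) declares a trajectory degenerate
  when even the one-cluster spread stays below it; the penalty then
  reduces to `1 + k` and the reported k = 2 is a label for "no cluster
  structure", not a discovery.

Cluster "average structures" are arithmetic coordinate means after
superposing every member onto the cluster's first frame; no geometry
idealization follows. The crystal-comparison step uses
`superpose()`/`segment_rmsd()` (global C-alpha fit, segment measurement,
matching by residue number and atom name with an optional renumbering
offset) as a superposition-based stand-in for local-global alignment
scoring; loop boundaries are plain selector arguments because loop
definitions vary between numbering schemes.

## The assay twin

The glycosylase-coupled assay is modeled end-point, per molecule:

1. the single special base at position 41 of an 80-nt 5′-labeled oligo
   deaminates with a per-reaction Bernoulli probability (C→U, 5mC→T,
   5hmC→5hmU); control substrates carrying U, T or 5hmU skip this step;
2. the glycosylase excises its eligible base (UDG: U; hSMUG1: U and
   5hmU; TDG: T opposite G, which requires the annealing step that
   builds the G:T mismatch duplex — calling TDG unannealed yields zero
   product);
3. alkali cleaves at the abasic site, and only the 5′-labeled 40-nt
   fragment is visible.

Excision and cleavage are deterministic and complete, mirroring their
role as saturating control steps; the only stochastic element is the
deamination draw, so the product fraction converges to the planted
efficiency. "Central position" of the 80-mer is position 41 (1-based),
forced by the 40-nt product length. Enzyme presets anchor wild type at a
per-reaction probability of 0.5 on C and 0.4 on 5mC and scale variants by
the published relative-activity ratios (R190X 140%/55%, R50A 20%/60%,
N51A 0%/78% on C/5mC; all presets zero on 5hmC) — these are fixture
values for simulation, not measurements, and `relative_activity()`
recovers the ratios independently of the anchors. Synthetic gel lanes add
multiplicative log-normal noise (σ = 0.05 by default) to band
intensities; lanes come in triplicate, matching the assay's replicate
structure. A detection limit (product fraction 0.01) is used only to
label outputs as detectable or not. Relative activity is the ratio of
replicate means × 100 with a delta-method standard deviation; the C-vs-5mC
relationship across variants is summarized by the Pearson product-moment
correlation.

## The NNCN pipeline

Four 104-nt oligos tile all 64 NNCN 4-mers (third base C): each oligo is
a 20-nt C-free flank + 16 contiguous motifs (64 nt) + a 20-nt C-free
flank — the only arrangement consistent with the arithmetic. Flanks are
forced C-free so primer-binding regions can never contribute events.
Because a motif's N slots may themselves be C, tiling creates incidental
C positions; every C position is indexed in its actual 4-mer context and
counted, since the deaminase acts on any C. The motif-to-oligo partition
is a seeded shuffle, deterministic per seed.

Clone reads are aligned by Needleman–Wunsch (match +1, mismatch −1, gap
−2) with a deterministic traceback tie-break (diagonal > up > left), and
each non-flank reference C becomes one event: unmutated, C→T,
other-substitution, or indel-adjacent (within one alignment column of an
indel — excluded from frequency denominators, since indels are attributed
to the polymerase). Frequencies are per-site: transitions divided by
eligible site × clone observations, aggregated across the four oligos,
with per-motif site counts preserved for audit; motifs with no eligible
observations are flagged absent rather than reported as zero. An
all-zero table over at least 20 clones raises a `no_detectable_activity`
summary flag. Opposite-strand G→A calls are out of scope: the assay
sequences the treated strand.

The clone generator flips each non-flank C to T with its motif's planted
probability and overlays a uniform substitution error at every position,
so a planted rate ε with zero deamination yields called C→T at ≈ ε/3 —
the background model the tests verify.

## Synthetic data: what it does and does not show

The generators plant exactly the statistics their analyzers recover:
distance series with exact min/max (endpoint frames) and exact mean,
interaction frames built on a 20 Å lattice so non-planted pairs sit ≥
1.5 Å beyond every threshold, cluster centers as random displacement
fields with a chosen separation-to-noise ratio, Bernoulli clone sets and
binomial gel lanes. All draws run in seeded local RNG streams that do not
touch the global generator state, so outputs are bit-identical per seed.

Passing tests therefore demonstrate that the *pipeline* is correct —
detectors match oracles, planted parameters are recovered within
statistical tolerance — not that real MD trajectories or real Sanger
reads would yield the published interaction counts or frequencies. In
particular, trajectory-level interaction inventories and model-vs-crystal
RMSDs depend on the original models and trajectories, which are not
regenerable here; the package encodes their qualitative signatures as
fixture designs instead. Synthetic flanks and fillers make no attempt at
sequence-composition realism beyond the C-free constraint, and the
clustered-trajectory generator produces displacement clouds, not
physically plausible conformational ensembles.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use sizes chosen to exercise
every code path at statistical power without waste: 10⁵ molecules per
simulated lane, 3 replicates and 50 seeds for activity recovery (binomial
error ≈ 0.2 percentage points on the recovered percent), 100 clones per
oligo for frequency recovery, 15–30-atom synthetic proteins with 4–6
frames per planted cluster for the clustering recovery sweep, and 200
random 20–80-atom fixtures for detector-oracle equivalence. Every
stochastic step takes an explicit seed; rerunning any function, test or
the acceptance script with the same seed reproduces its output exactly.

## Known limitations

* No energetics anywhere: contacts are geometric, hydration is two
  constants, and deamination is a single end-point probability (no
  kinetics, processivity or sliding).
* The PDB reader handles coordinates only (ATOM/HETATM/MODEL records,
  first altloc rules, no insertion codes); mmCIF, compressed
  trajectories and header metadata are out of scope.
* Interaction cutoffs are conventions; absolute counts shift with them,
  which is why the package's claims are anchored to planted fixtures and
  configurable thresholds rather than to cutoff-sensitive reproduction.
* The Needleman–Wunsch aligner is quadratic and intended for
  clone-length (~100 nt) reads, not genome-scale alignment.
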