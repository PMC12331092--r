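---
title: "Quantifying the arrestin arginine-switch intermediate: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the arrestin arginine-switch intermediate: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrswitch)
```

## The scientific problem

β-arrestin-2 (βarr2) is locked in its inactive state by a buried network of
charged residues — the *polar core* (Asp27, Arg170, Asp292, Asp299,
Arg394) — and by the three-element interaction that pins its C-terminal
tail. Activation by a phosphorylated receptor C-tail proceeds through an
intermediate in which Arg394, the only residue bridging the N-domain,
C-domain and C-tail, rotates out of the polar core. In this "arginine
switch" picture, a receptor-tail glutamate (Glu358 of the CXCR7-derived
C7pp2 phosphopeptide) captures the displaced Arg394 and thereby stabilises
a broken polar core.

`arrswitch` implements the quantitative analyses that characterise this
intermediate:

1. **Geometric observables over MD replicate ensembles** — salt-bridge
   distance series, contact-stability fractions, polar-core integrity and
   engaged/disengaged state classification, and per-residue RMSF.
2. **Conformer clustering** — greedy quality-threshold (QT) clustering of
   switch-residue conformations by heavy-atom RMSD.
3. **Condition statistics** — two-sided Mann–Whitney U comparisons of
   distance distributions and Tukey boxplot summaries.
4. **Two-site binding isotherms** — a forward model and nonlinear
   least-squares fits for biphasic titration calorimetry, with F-test
   model selection.
5. **Differential HDX-MS** — the significance rule p < 0.05 AND
   |Δuptake| ≥ 0.2 Da, with peptide-level region classification.
6. **Synthetic data generators** — seed-deterministic fixtures with ground
   truth, so every stage is testable without external downloads.

## Trajectory model and atom selections

Trajectories are frames × atoms × 3 coordinate arrays (Å) bound to an
ordered atom table carrying author residue numbering (Arg394 is residue
394 as in rat βarr2; the peptide uses CXCR7 numbering 346–359). Multi-model
PDB is the canonical format — it is self-contained and text-based — with
DCD supported behind the same interface; parsing and writing go through
`bio3d`. Phosphoserine/phosphothreonine are recognised either by residue
names `SEP`/`TPO` or by a phosphorus atom in a SER/THR record.

Selections use a small conjunctive grammar
(`"resid 394 and name CZ"`, `"resid 350 352 and name P"`): clauses
(`resid`, `resname`, `name`, `chain`) are ANDed, values within a clause are
ORed. This is deliberately minimal — it covers every selection the analyses
need while staying trivially deterministic.

In this R implementation all indices (atoms, frames, clusters) are 1-based,
following the language's convention.

Superposition is the standard least-squares (Kabsch) rigid-body fit; it
requires at least three non-collinear atoms and never alters internal
geometry. Because the source simulations restrain the arrestin backbone,
most analyses here run in the simulation frame without refitting.

## Geometric observables

**Monitoring distances.** Site-I contacts are monitored between the
phosphorus atom of the phosphoresidue and the guanidinium carbon (Cζ) of
the partner arginine; site II between Cδ of the peptide glutamate and Cζ of
Arg394. These single-atom ("specific") series reproduce the monitoring
convention of the source ensembles.

**Contact stability.** The stability percentage of a salt bridge is the
fraction of frames in which the contact is formed. The formation criterion
is not part of the monitoring convention, so the package defines it
explicitly: minimum distance between side-chain acidic/phosphate oxygens
and basic side-chain nitrogens ("min-group" mode) at a 4.0 Å cutoff — the
standard salt-bridge criterion. Both the criterion atoms and the cutoff are
configuration-exposed, because reported stability percentages from other
pipelines may use a different rule or analysis window.

**Polar-core integrity.** Measured as Cζ(Arg394)–Cγ(Asp299), i.e. the
charged-group carbons, matching the carbon-atom convention used for the
site-II monitoring distance. Small values (≲6 Å) indicate an intact core
(inactive-like), large values (~10 Å) a disrupted core (intermediate). The
default engaged/disengaged threshold is 6.0 Å — between the ~6 Å
re-formed-bridge regime and the ~10 Å disrupted regime — and is
configurable.

**Analysis windows.** Stability ensembles are analysed over all frames;
relaxation ensembles over the equilibrated tail ("last 50 ns"), selected
via per-frame times.

**RMSF.** Per-atom root-mean-square fluctuation about the time-averaged
position. The reference is the time-averaged structure after two passes of
iterative superposition (frame 1 seeds the first pass); with multiple
replicates the per-replicate profiles are averaged. Alignment can be
disabled for backbone-restrained or synthetic lab-frame data. For isotropic
per-atom jitter of width σ the expected RMSF is σ√3 — the closed form used
as an oracle in the tests.

## Quality-threshold conformer clustering

Frames are clustered on the switch arginine's heavy atoms: one global
superposition (optional, for unrestrained data), then pairwise RMSD
*without* per-pair refitting — per-pair fitting would discard exactly the
positional signal being classified. The clusterer is the classic greedy QT
heuristic: repeatedly seed a cluster at the frame with the most unassigned
neighbours within the cutoff (ties → lowest frame index), assign seed and
neighbours, remove, repeat. Cutoffs follow the two analysis regimes:
3.7 Å for C-tail rebinding ensembles and 1.0 Å for relaxation ensembles.
Greedy QT guarantees that cluster sizes are non-increasing and that every
member is within the cutoff of its centre; the test suite checks the
implementation against an independent exhaustive re-implementation on
random instances. Pooled frames across replicates are the default unit of
clustering (per-replicate clustering then merging is a config choice the
caller can make by clustering each replicate separately).

## Condition statistics

Distance distributions between conditions are compared with the two-sided
Mann–Whitney U test. Observations are pooled per-frame distances — matching
how the distributions are visualised as boxplots — with the caveat that
frames within a replicate are autocorrelated, so the p-values are
descriptive rather than strictly calibrated; a per-replicate-mean mode can
be obtained by passing replicate means instead. The exact null distribution
is used when min(n₁, n₂) ≤ 10 without ties; otherwise the normal
approximation with continuity and tie correction. Boxplot summaries follow
the Tukey convention (linear-interpolation quartiles, whiskers at the most
extreme data within 1.5 × IQR, outliers beyond).

## Two-site binding isotherms

A biphasic calorimetric titration is modelled as two *independent* classes
of sites with dissociation constants K_D1 ≤ K_D2 (site I = high affinity)
and per-site molar enthalpies. For each injection the cell totals are
updated with displacement-dilution bookkeeping (injection volume v into
cell V₀ dilutes prior contents by 1 − v/V₀), the free-ligand concentration
is solved from the mass balance

  L + M·(n₁L/(K_D1+L) + n₂L/(K_D2+L)) = L_total

by bracketed bisection on [0, L_total] (relative tolerance 10⁻¹²; the left
side is strictly increasing, so the root is unique), and the reported heat
per mole of injectant applies the displaced-volume correction
(Q_i − Q_{i−1} + (v_i/V₀)(Q_i + Q_{i−1})/2)/n_injected.

Fitting is Levenberg–Marquardt least squares on log-K_D (positivity),
enthalpies and a baseline offset, with stoichiometries fixed at 1 per site
class. Because biphasic curves have local minima, fits use eight
multi-starts with the dissociation constants jittered geometrically (×/÷3
and wider) around a heuristic start (transition position → K_D scale,
first-injection heat → ΔH).

**Model selection.** Two-site vs one-site uses the extra-sum-of-squares F
test (2 extra parameters) plus two identifiability screens, all three
required to claim a second site:

* each site's *heat signal* — |ΔH_k| times the swing of that site's
  fractional occupancy over the titration — must exceed 3× the residual
  standard deviation (a site invisible in the heats cannot be claimed);
* each fitted K_D must lie within 10× the final total ligand
  concentration: beyond the titrated range the classic degenerate fit is a
  quasi-linear pseudo-site with an enormous compensating enthalpy, pure
  extrapolation that the F test alone does not reject.

The screens were calibrated on held-out null simulations (one-site data at
2% heat noise), where the F test alone mislabels a few percent of datasets;
with both screens the empirical false-two-site rate on the calibration sets
is zero while genuine biphasic data (site signals ≳20× the noise floor)
is unaffected.

**Experiment geometry.** The default experiment is a 200 µL cell with
200 µM arrestin titrated by 25 × 2.5 µL injections of 1 mM peptide at
298 K. A caveat this package makes explicit: with a 5:1 syringe-to-cell
concentration ratio and this injection schedule the titration reaches a
molar ratio of only ~1.9 — below saturation of two site classes — and a
local (Fisher-information) analysis at 2% heat noise shows the relative
standard deviation of K_D1 exceeds 30% under *any* reasonable geometry of
this titration (and ~100% at the default one). Noiseless round trips
recover both constants to <0.1%, but noisy single-experiment K_D estimates
at this noise level are intrinsically uncertain; the tests document this
honestly rather than papering over it.

## Differential HDX-MS

Uptake tables carry replicate deuterium uptake (Da) per peptide, state and
exchange time (10/100/1000/10000 s, n = 3). For each peptide × timepoint
the difference Δ = mean(B) − mean(A) is tested with a pooled-variance
two-sample Student t test; a difference is significant only if p < 0.05
AND |Δ| ≥ 0.2 Da. The 0.2 Da floor encodes the practical resolution of
centroid-based uptake measurement: a statistically tight but sub-resolution
difference is never called. With two groups the pooled t test is exactly
equivalent to a one-way ANOVA (F = t²) — the suite asserts this — so either
description of the procedure yields identical calls. No multiple-testing
correction is applied across peptides by default (a Benjamini–Hochberg
option exists); the magnitude floor already suppresses most spurious calls.
Peptides are then classified "increased" / "decreased" / "ns" / "mixed" by
the direction of their significant timepoints. Back-exchange is not
corrected — the analysis compares states measured identically.

## Synthetic data: what it emulates, and what it does not

The switch simulator is a first-order, frame-discrete two-state Markov
chain driving a pseudo-molecule that contains only the atoms the metrics
read (the gate and anchor aspartates, site-I arginines and phosphoresidues,
the peptide glutamate, and the switch arginine). Engaged frames place
Cζ(R394) 3.9 Å from Cγ(D299) (intact core); disengaged frames place it
10 Å away and 4.2 Å from Cδ(E358) (peptide-captured). Every atom receives
isotropic Gaussian noise (σ = 0.2 Å). The defaults emulate the two
polar-core regimes of interest: mostly-disengaged dynamics for the
peptide-bound intermediate (~10 Å mean switch–gate distance) and
re-engaging dynamics for apo/E358A conditions (~6 Å mean).

The ITC generator adds i.i.d. Gaussian noise (a stated fraction of the
maximum |heat|) to the forward model; the recovery studies use the two
mutant-isolated dissociation constants (1.1 and 16.4 µM) as generating
truth since the wild-type pair is not separately reported. The HDX
generator uses single-exponential exchange D(t) = N(1 − e^{−k_int t / P})
with state-dependent protection factors and 0.05 Da replicate noise; the
default panel mirrors the regions of interest (gate loop 292–302 and
C-strand 382–389 gaining exchange on binding; central loops 119–133,
283–291, 305–317 losing it; two unchanged controls).

What the generators deliberately do **not** emulate: full-protein geometry,
kinetic realism (no inertia or friction — the pipeline never uses
velocities), correlated atomic motions, multi-exponential amide exchange
within a peptide, or instrument baseline drift. Passing tests therefore
demonstrate correctness of the *analysis* (classification, fractions,
clustering, fitting, significance calls against known truth), not fidelity
of any molecular mechanics. Statistics on real deposited trajectories
additionally depend on the contact criterion and analysis window, which is
why both are config-exposed.

## Numerical choices

* Free-ligand bisection: 80 halvings of [0, L_total] (≤10⁻¹² relative).
* QT ties broken by lowest frame index; populations in percent sum to 100
  (± unassigned pool under `max_clusters`).
* RMSD matrices are computed via Gram-matrix expansion with negative
  round-off clamped at zero.
* Optimiser: `minpack.lm::nls.lm`, ftol = ptol = 10⁻¹⁴, ≤200 iterations
  per start; the best of eight starts is reported, and a fit is
  `converged` if the optimiser reports a gradient/ftol criterion.
* Degenerate inputs fail loudly: empty selections warn, empty frame sets,
  non-symmetric matrices, collinear fit selections and missing atoms are
  errors that name the offending entity.

## Problem sizes in the shipped analyses

The `analysis/` drivers and the acceptance script run the whole chain on
synthetic data sized for a desk machine: 5 replicates × 300–1500 frames per
condition, 2000 pooled frames for clustering (the pipeline subsamples
pooled ensembles beyond `cluster_max_frames = 2000` with an even stride),
25-injection isotherms, and the 7-peptide HDX panel — sizes at which every
stage completes in minutes while leaving the statistical behaviour of each
estimator clearly visible.

## Known limitations

* Pooled-frame Mann–Whitney p-values ignore within-replicate
  autocorrelation (see above).
* The two-site model is independent-sites only; sequential/cooperative
  binding and global multi-experiment fitting are out of scope.
* Single-experiment K_D uncertainty at realistic heat noise is large (see
  the geometry caveat); mutant-isolated one-site fits are far better
  conditioned than the biphasic two-site fit.
* HDX analysis starts from uptake tables; spectral processing and
  back-exchange correction are upstream concerns.
* DCD reading is supported but optional; XTC/TRR are not.
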