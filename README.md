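# arrswitch

Analysis pipeline for characterising the **arginine-switch activation
intermediate of β-arrestin-2 (βarr2)** from molecular-dynamics replicate
ensembles, titration calorimetry and hydrogen/deuterium exchange.

## The problem

Inactive βarr2 is locked by its *polar core* — a buried charge network
(Asp27, Arg170, Asp292, Asp299, Arg394) — and by the three-element
interaction holding its C-terminal tail. Activation by a phosphorylated
receptor tail proceeds through an intermediate in which **Arg394** (the
"arginine switch", the one residue bridging N-domain, C-domain and C-tail)
rotates out of the polar core and is captured by a glutamate of the
receptor phosphopeptide (Glu358 of the CXCR7-derived peptide C7pp2). This
package provides the quantitative machinery to detect and characterise that
intermediate, for structural biologists and simulators working on
arrestin/GPCR activation:

* **Trajectory model** — multi-model PDB (and DCD) reading/writing via
  `bio3d`, a small deterministic atom-selection grammar
  (`"resid 394 and name CZ"`), Kabsch superposition, replicate sets and
  `"last T ns"` analysis windows.
* **Switch metrics** — salt-bridge distance series (specific-atom or
  min-group), contact-stability fractions (fraction of frames with the
  contact formed, min O···N ≤ 4 Å), polar-core integrity as
  Cζ(R394)–Cγ(D299) distance, engaged/disengaged classification
  (threshold 6 Å), and per-residue RMSF about the two-pass iteratively
  superposed mean structure.
* **Conformer clustering** — greedy quality-threshold clustering on the
  switch residue's heavy-atom RMSD (cutoffs 3.7 Å / 1.0 Å for
  rebinding / relaxation ensembles), with populations and representative
  frames.
* **Statistics** — two-sided Mann–Whitney U (exact for small untied
  samples), Tukey boxplot summaries.
* **Two-site ITC** — forward model for two *independent* site classes
  (K_D1 ≤ K_D2: site I high affinity, site II low affinity), free ligand
  from the mass balance `L + M·Σ n_k L/(K_Dk + L) = L_tot` by bisection,
  Levenberg–Marquardt multi-start fitting, and F-test model selection with
  identifiability screens.
* **Differential HDX-MS** — per-peptide, per-timepoint pooled-variance
  Student *t* with the significance rule **p < 0.05 AND |Δ| ≥ 0.2 Da**,
  and region classification (increased / decreased / ns / mixed).
* **Synthetic data** — seed-deterministic generators (two-state Markov
  switch trajectories, noisy biphasic isotherms, exponential-exchange HDX
  panels) that return ground truth, so the whole pipeline is testable
  offline.

## Worked example

The `analysis/` directory holds the numbered drivers of the full workflow.
`analysis/01_simulate.R` writes synthetic study data under
`results/synthetic/` (three simulated conditions × 5 replicates, a
rebinding ensemble, three isotherms, an HDX panel — all with recorded
ground truth); the later stages analyse it:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_switch_metrics.R
```

```
--- polar-core summary ---
IM_C7pp2  mean switch-gate distance  9.82 A, engaged fraction 0.030
apo       mean switch-gate distance  6.88 A, engaged fraction 0.515
E358A     mean switch-gate distance  6.91 A, engaged fraction 0.509

--- condition comparisons (two-sided Mann-Whitney U) ---
IM_C7pp2 vs apo        p = 3e-112
IM_C7pp2 vs E358A      p = 1.89e-106
apo vs E358A           p = 0.937
```

The peptide-bound intermediate keeps its polar core disrupted (mean
switch–gate distance ≈ 10 Å, almost no engaged frames); removing the
peptide or its glutamate anchor lets the Arg394–Asp299 salt bridge re-form
in half of the frames (mean ≈ 6–7 Å), and the Mann–Whitney test separates
the bound condition from both relaxing ones while the two relaxing
conditions are indistinguishable.

```sh
Rscript analysis/04_itc.R
```

```
--- wt ---
preferred model: two_site (F-test p = 8.11e-10)
kd1 = 0.93 uM, kd2 = 19.10 uM (dh1 = -7.43, dh2 = -3.79 kcal/mol)

--- R394A ---
preferred model: one_site (F-test p = 0.785)
kd = 1.05 uM (dh = -7.84 kcal/mol)
```

The biphasic "wild-type" isotherm (generated with K_D = 1.1 / 16.4 µM and
2% heat noise) is recognised as two-site and both constants are recovered;
each single-site "mutant" isotherm — emulating the loss of one binding
phase — is preferred as one-site with its constant recovered.

`analysis/03_clustering.R` clusters the rebinding ensemble (two QT clusters
whose populations match the generator's engaged/disengaged fractions) and
`analysis/05_hdx.R` classifies the HDX panel (gate-loop 292–302 and
C-strand 382–389 "increased"; loops 119–133, 283–291, 305–317 "decreased";
controls "ns").

## Layout

```
R/                  package code (trajectory model, metrics, clustering,
                    stats/HDX, ITC, generators, pipeline orchestration)
analysis/           numbered workflow drivers (simulate -> metrics ->
                    clustering -> ITC -> HDX), writing under results/
scripts/acceptance.R  headline-quantity recomputation (JSON)
tests/testthat/     unit, property and acceptance tests with independent
                    oracles (enumeration, closed forms, brute force)
vignettes/          methods vignette: models, assumptions, parameter
                    defaults, limitations
```
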