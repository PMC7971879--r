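---
title: "blastosem: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{blastosem: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

blastosem simulates preimplantation mouse development from the fertilized
egg to the late 128-cell blastocyst in three dimensions, coupling three
layers: a stochastic gene-regulatory network in every cell, particle-based
cell mechanics with cell-type-selective adhesion, and external constraints
(zona pellucida, blastocoel cavity). This vignette documents the model,
the defaults, and the reasoning behind every numerical choice that the
package had to make on its own.

## The gene-regulatory layer

Each cell carries concentrations of Nanog, Gata6, Fgfr2, Fgf4 and active
Erk, all non-dimensional. The drift has the classic mutual-antagonism
architecture of the Epi/PE decision:

* Nanog: basal synthesis `vsn0`, an Erk-inhibited term
  `vsn1 Kin1^u / (Kin1^u + (eps_t Erk)^u)`, cooperative self-amplification
  gated by Gata6 (`Kin2`), linear decay.
* Gata6: basal synthesis, an Erk-promoted term (`vsg1`, `Kag1`),
  self-amplification gated by Nanog (`Kig`), linear decay.
* Fgfr2: repressed by Nanog, promoted by Gata6; Fgf4: activated by Nanog;
  Erk: activated at rate `va * Fr * Fp/(Kd+Fp)` with a saturating
  `(1-Erk)` ceiling and Michaelis-Menten deactivation, which confines Erk
  to [0, 1] in the zero-noise limit.

Cells communicate only through perceived Fgf4: cell i receives
`sum_j (1+gamma_j) Fs_j / N_j` over neighbors j within the contact radius,
where `N_j` is the sender's neighbor count (each cell distributes its
ligand equally among its contacts) and `gamma_j` is a small Gaussian
perception noise (sd 0.1, clamped so the flux stays nonnegative). The
control parameter `eps_t` gates both Erk-dependent terms and implements
the Fgf-signaling schedules (on/off stages); `eps_t = 0` removes the
coupling entirely.

Integration is Euler-Maruyama with multiplicative noise
(`sigma_X * X * sqrt(dt) * eta`) and post-step clamping at zero -- the
simplest scheme consistent with proportional expression noise; the test
suite verifies first-order convergence of the zero-noise limit against an
adaptive-step integrator.

### How the default rate constants were chosen

No complete published constant set was available to this package, so the
defaults were tuned, once, to make the deterministic attractor landscape
match the biology the model is meant to reproduce:

1. with signaling off (`eps_t = 0`) the only attractor reachable from
   co-expressing (double-positive, DP) states is Nanog-high -- Fgf
   signaling is required for any Gata6+ cells to exist;
2. with signaling on, the Nanog-high branch is stable at low perceived
   Fgf4 and loses stability as Fp rises, so a population of secreting
   cells self-organizes into a Nanog+/Gata6+ mixture whose ratio is set
   by where secretion balances the branch stability (about 40/60 at the
   default constants);
3. a committed Gata6-high cell at `eps_t = 0` is *metastable*: it reverts
   to Nanog-high through a slow saddle-node ghost with a transit time of
   about 10 time units, independent of Fp. This single timescale
   reconciles two observations: attenuating signaling when the 128-cell
   stage is reached preserves the Nanog+/Gata6+ ratio through the short
   terminal sorting window, while switching signaling off at the 64-cell
   stage (two cleavage rounds before the end) gives reverted, almost
   purely Nanog+ embryos.
4. Fgfr2 accumulates slowly (`kFr = 0.12`, a ~8 time-unit timescale,
   seeded low in the zygote) and acts as the developmental clock: Erk
   responsiveness, and with it lineage commitment, ramps up around the
   32-64-cell stages rather than in the cleavage-stage embryo. Fgf4
   itself turns over fast (`kFs = 1`), so the lateral-inhibition feedback
   tracks the current secretor pool and self-limits the Gata6+ fraction.

All constants sit in `default_parameters()` and any can be overridden
from code or YAML. Hill exponents are 4 for the transcriptional
antagonism/self-amplification terms (sharp, switch-like) and 2 for the
receptor/signaling terms (graded).

Fate classification uses thresholds `theta_N = 1.8`, `theta_G = 0.8`,
placed in the gap between the committed-low and committed-high modes of
the endpoint marginal distributions of the default parameterization
(Nanog-high cells settle near 2.9, basal near 0.1-0.9; Gata6-high near
1.7-3.2, basal near 0.05-0.6). The thresholds are configuration values,
not printed constants.

### Oct4/Cdx2 and the first lineage decision

Before the blastocyst stage each cell also carries a bistable
Oct4/Cdx2 toggle (mutual antagonism with self-activation) whose basal
production is biased by cell contact: the contacted share of a cell's
elements (1 = fully interior) feeds a sigmoidal bias that favors Oct4
inside and Cdx2 outside. The exact published form of this subsystem was
not available; the implementation is a standard toggle held behind the
`te_icm_step()` contract, and only its fixed-point structure (interior ->
Oct4, exterior -> Cdx2) is relied on. When the embryo reaches 32 cells
the toggle runs for a short burn-in (2 time units) with the 32-cell
geometry and the decision is frozen: `Cdx2 > Oct4` becomes TE, the rest
ICM. After the freeze the Epi/PE network and Fgf4 exchange run in the
ICM only, reflecting Cdx2-mediated repression of the ICM program in TE.

## The mechanical layer

Cells are clouds of subcellular elements (default 20 per cell; scaled
runs use fewer). Elements interact through Morse pair potentials:
same-cell pairs with a deep well (cohesion), different-cell pairs with a
shallower well whose *attractive term only* is multiplied by the adhesion
score of the two cells' types -- low adhesion weakens stickiness but
never licenses interpenetration. The published functional forms of the
potentials were not available; Morse is the standard choice in the
subcellular-element literature. Element motion is overdamped with
additive Gaussian movement noise; the deterministic displacement per step
is capped at a quarter of the element spacing so that the steep core
after division replenishment cannot destabilize the integration (the cap
preserves the downhill direction, and the energy-decrease property is
verified in tests).

Lengths are non-dimensionalized by the zona pellucida radius. Cleavage
conserves embryo volume, so the nominal cell radius is
`0.95 n^(-1/3)` and all interaction ranges (element spacing, Morse
equilibria, the gene-signaling contact radius, the outcome-classifier
adjacency radius) are expressed as stage-dependent multiples of it. The
Morse range parameter is likewise given in inverse element spacings so
that the relative core width is stage-invariant. The inter-cell
equilibrium spacing is 1.2x the intra-cell spacing: enough contrast to
keep cells coherent and distinct (identical spacing lets clouds of
elements mix into a single mass; much larger values produce a hollow,
under-packed embryo).

External forces: a linear restoring force confines elements inside the
zona; after the embryo reaches 32 cells, an exclusion sphere anchored at
the lower pole (center z = -0.45) grows linearly over three cleavage
intervals to radius 0.5 and pushes elements out -- a geometric stand-in
for blastocoel inflation that sweeps the ICM against the opposite pole of
the TE shell.

Division splits a mother's elements by a random plane through its
centroid (median split, so both daughters are nonempty), copies the gene
state, and immediately replenishes each daughter to the target element
count by jittered duplication; immediate replenishment is a design
choice (the alternative -- growth over the cycle -- is not observable at
the questions this package asks). Rounds are synchronous to the 32-cell
stage; the 32-to-64 and 64-to-128 rounds draw per-cell division times
uniformly in a window of 3-7 time units after the previous round
completes. One cleavage interval is 4 time units, which sets gene-network
kinetics (decay rate 1) a few-fold faster than the stage clock; the run
ends a 5-unit sorting window after the 128th cell appears.

## Adhesion scores

Data-informed scores: for cell types i, j with mean ligand/receptor
levels `[L]`, `[R]`, the unnormalized score is
`(([L]_i [R]_j + [L]_j [R]_i)/2)^n_force`, normalized by the DP-DP score,
with `n_force = +1` for adhesion-strengthening pairs (EphA4/EphrinB2) and
`-1` for weakening pairs (EphB2/EphrinB2). The mean is taken over raw
levels; the log1p transform enters only the per-cell visualization score
that is binarized by the two-component Gaussian mixture (EM via mclust).
The phenomenological hypotheses H1-H5 use baseline 1 and boost 2 for
favored pairs -- magnitudes are not the claim surface, orderings are, and
both are exposed in configuration. TE pairings are not measurable from
ICM-restricted expression data and instead implement the assumption that
TE adheres more strongly to Epi-fated than to PE-fated cells.

## Pattern evaluation

The ICM pole is `r xbar/||xbar||` with `xbar` the mean ICM position and
`r` the mean TE distance from the embryo center; the ideal pattern labels
the `n_epi` pole-closest ICM cells Epi (ties broken by cell index) and
the rest PE. The loss score matches misplaced Epi against misplaced PE
cells by minimum-cost bipartite matching (a shortest-augmenting-path
Hungarian solver written for this package, as no installed R package
provides weighted bipartite matching; it is tested against a brute-force
permutation oracle) and normalizes by the mean cost of 200 random
labelings with the same Epi count -- random preserves the Epi count so
the two mismatch sets stay equal in size. Model Epi is defined as
Nanog-high (Nanog+ or DP) and the rest PE. Outcome classification builds
the Epi adjacency graph at 2.4 cell radii and requires a single attached,
PE-covered aggregate for success; coverage asks each Epi cell to be
shielded toward the cavity center by an adjacent PE (or deeper Epi) cell,
with threshold 0.8. The adjacency radius and coverage threshold are
package choices (the source definitions are verbal) and sit in
configuration.

Under persistent (never-attenuated) signaling the reported
"Nanog-high cells highly expressing Gata6" fraction is
`DP / (DP + Nanog+)` -- cells above both thresholds -- because continued
Erk drive in aggregated Nanog-high cells re-elevates Gata6; with
attenuation at the 128-cell stage this fraction collapses to zero. The
scenario runners report it as a cell-level percentage pooled over
replicate embryos: per-embryo denominators are only a handful of cells
and would give each surviving cell in a nearly-converted embryo an
outsized weight.

## The synthetic-data generators

`synth_adhesion_expression()` emulates the statistical structure of the
adhesion-gene observations: each cell is high- or low-adhesive with a
fate-dependent probability (defaults 0.8 / 0.75 / 0.35 for Nanog+ / DP /
Gata6+ -- the measured ordering "fewer Gata6+ cells highly express the
pair"), and ligand/receptor levels are lognormal within mode (meanlog
log 30 vs log 3, sdlog 0.35/0.45), which makes the combined log1p z-score
visibly bimodal. `synth_initial_states()` draws fate-conditional
lognormal (Nanog, Gata6) clusters in model units, sets Fgfr2/Fgf4 at
their quasi-steady values given those, and solves the Erk quasi-steady
state at a nominal perceived Fgf4 of 0.5. What these generators do *not*
emulate: transcriptome-wide covariance, dropout, library-size variation,
batch structure. Tests passing on synthetic data therefore certify the
estimators and the model plumbing, not robustness to real scRNA-seq
artifacts; the loaders accept real matrices wherever the synthetic ones
are used.

## Problem sizes and degenerate inputs

The package's own validation runs use 8 elements per cell, 6-10
replicates per condition, and 128-cell endpoints -- enough for stable
population fractions (ICM of 25-45 cells) while keeping a full run in
seconds. Degenerate inputs are handled explicitly: empty neighborhoods
perceive zero Fgf4; coincident elements are regularized by a 1e-6
minimum pair distance; a zero mean-ICM position (pole undefined), an
all-TE embryo, constant expression scores, and a zero DP-DP
normalization anchor all raise informative errors rather than producing
numbers.

## Known limitations

A note on the no-signaling control: with the Erk coupling disabled the
deterministic flow collapses every co-expressing cell to a single
dominated fate, so no Nanog+/Gata6+ separation arises without Fgf
signaling. With expression noise and basal Gata6 synthesis tuned near
the separatrix, a knife-edge race can still split a population -- but
the split fraction then tracks the basal rates rather than any
feedback, i.e. there is no ratio control without the signaling loop.


* The Oct4/Cdx2 subsystem, the potentials and the external-force forms
  are principled stand-ins for unavailable published detail; their
  parameters are conventions of this package.
* No cell polarity, contractility or blastocoel fluid mechanics; the
  cavity is purely geometric. A consequence: the TE monolayer is not
  actively maintained after the 32-cell decision, and because TE-TE
  adhesion is the strongest pairing, differential-adhesion sorting can
  draw TE cells toward the interior of the compacted cell mass late in
  the simulation. The Epi/PE pattern metrics are computed over ICM cells
  and are insensitive to this artifact; analyses of TE geometry past the
  decision stage should not rely on the default mechanics.
* The Nanog/Gata6 program is switched off in TE cells after the 32-cell
  decision rather than being actively repressed by a modeled Cdx2 arm.
* Fate ratios at the endpoint carry replicate-to-replicate spread of
  several percentage points at these population sizes; conclusions should
  be drawn from replicate means, as the scenario runners do.
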