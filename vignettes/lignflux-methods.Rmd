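---
title: "Compartmental steady-state flux and 13C-label analysis of monolignol biosynthesis"
author: "lignflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental steady-state flux and 13C-label analysis of monolignol biosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignflux)
```

## The problem

Lignin is deposited from three hydroxycinnamyl alcohol monomers -- H
(*p*-coumaryl), G (coniferyl) and S (sinapyl) alcohol -- produced by the
phenylpropanoid pathway.  In the grass *Brachypodium distachyon* the
pathway is fed by two amino-acid precursors, phenylalanine (via PAL) and
tyrosine (via TAL), which contribute almost equally to total lignin yet
end up preferentially in different monomers: phenylalanine-derived carbon
is enriched in G units and tyrosine-derived carbon in S units, although
both routes converge at *p*-coumaric acid.  Three of the pathway enzymes
(C4H, C3'H, F5H) are bound to the outer surface of the endoplasmic
reticulum while the rest are cytosolic, so several intermediates exist as
parallel cytosol/ER pools that exchange by diffusion.

`lignflux` implements the analysis that turns this qualitative puzzle
into a quantitative model-selection exercise: which compartmental wiring
of the pathway can simultaneously reproduce

* the lignin monomer composition (H/G/S percentages and the S/G ratio),
* the ^13^C incorporation levels measured when 35% of either precursor
  is fed in fully labeled form, including wall-bound ferulic and
  *p*-coumaric acid,
* and the *differential* incorporation of the two precursors?

Three shipped network encodings represent the competing hypotheses:
`brachy_fig4` (compartments only), `brachy_fig5` (compartments plus a
long direct channel from ER *p*-coumaroyl-CoA to coniferyl alcohol) and
`brachy_fig6` (compartments plus the shortest channel, a CCR/CAD complex
acting on an ER-resident feruloyl-CoA route, flux id `V_8`).  A small
`illustration` network (two inputs, one diffusion pair, two branch
points) is shipped for exposition and testing.

## Steady states from flux split ratios

A network with metabolite vector $X$ and flux vector $V$ obeys
$\dot X = S\,V$ with $S$ the signed incidence (stoichiometric) matrix;
the pathway is monomolecular throughout, so every entry of $S$ is $-1$,
$0$ or $+1$.  At steady state $S\,V = 0$ is underdetermined: there are
more fluxes than internal pools.  Rather than imposing a cellular
objective function (as flux balance analysis would), the admissible space
is parameterized by *flux split ratios* (FSRs): at every metabolite with
$k \ge 2$ outgoing edges, the fractions of its total inflow routed to
each edge.  Each $k$-way branch contributes $k-1$ degrees of freedom;
`branch_points()` enumerates them.  Given split ratios, fluxes follow by
propagation down the (acyclic) net-flux graph, and $S\,V = 0$ holds by
construction (`fluxes_from_fsr()`).

Monte-Carlo exploration (`sample_admissible_fluxes()`) draws every branch
uniformly: $\mathrm{U}[0,1]$ for two-way branches, flat Dirichlet on the
simplex for wider ones.  Inputs are normalized to 100 units of mass per
unit time each (the absolute input magnitude is unknown; all constrained
observables are scale-free percentages, and the tests verify this
invariance).  Draws are screened against non-negativity and against the
constraints computable from total fluxes: monomer composition, S/G, and
flux-ratio targets.

## Label balances and bidirectional diffusion

A scalar enrichment $L_i \in [0,1]$ (the labeled fraction of pool $i$)
suffices to track a uniformly ^13^C-labeled precursor; positional
isotopomers are out of scope.  Every efflux of a pool carries that pool's
enrichment, so for a pool outside any diffusion pair the steady-state
label is simply labeled inflow over total inflow -- fully determined by
upstream values.

Diffusion between a cytosol pool and its ER partner is different: the
net edge of the steady-state model hides two opposing unidirectional
components $D_f$ (along the net direction) and $D_r$ (against it), and
label can ride both.  Writing total and labeled balances for the pair
(illustration-network notation, pool 2 with inflow $V_1$ and outflow
$V_2$, partner pool 4):

$$V_1 + D_r = V_2 + D_f, \qquad
  L_1 V_1 + L_4 D_r = L_2 (V_2 + D_f),$$

and the analogous balances at pool 4, gives, after eliminating the
exchange, the partner label

$$L_4 = \frac{L_2 V_2 - L_1 V_1 - L_3 V_3}{V_2 - V_1 - V_3}
  \quad\text{(\texttt{partner\_label()})},$$

and then

$$D_r = \frac{(L_2 - L_1)V_1}{L_4 - L_2}, \qquad
  D_f = \frac{(L_4 - L_1)V_1}{L_4 - L_2} - V_2
  \quad\text{(\texttt{resolve\_diffusion()})},$$

with $D_f - D_r$ equal to the net flux identically.  One label per pair
is genuinely free; the package samples it and derives everything else.
The labeled part of each flux is its source pool's enrichment times its
magnitude (`split_labeled_fluxes()`); note that the net labeled
diffusion is $L_2 D_f - L_4 D_r$, *not* $L_2(D_f - D_r)$ -- the two
differ by $(L_2 - L_4)D_r$, which is why the bidirectional resolution is
required at all whenever the paired pools are unequally enriched.

The test suite checks this algebra two independent ways: against a
hand-evaluated numeric chain ($L_4 = 19/120$, $D_r = 360$, $D_f = 380$
for the documented inputs) and against a Newton solve of the raw node
balances that never performs the closed-form elimination.

### Sampling order and degeneracies

Pool pairs are resolved jointly, in a *pair-condensed* topological order:
both pools of a pair become available only when the pair is resolved, so
any consumer of either pool is processed afterwards.  (A plain
metabolite-level order is not sufficient -- a consumer of the cytosol
member may otherwise be visited before the ER member's balance closes.)

For the sampled member of each pair the admissible enrichment interval
is known in closed form: one endpoint is the zero-exchange value
($D_r = 0$), the other the complete-mixing value
$M = \text{total labeled inflow}/\text{total outflow}$ of the pair.  The
uniform draw $u \in [0,1]$ is therefore placed directly on this interval
-- $u = 0$ meaning no exchange and $u = 1$ complete mixing -- instead of
proposing on all of $[0,1]$ and rejecting; with several pairs in series
the naive proposal wastes all but $\sim 10^{-6}$ of draws while the
placed draw explores exactly the same support.  Infeasibility signals
(a label outside $[0,1]$, a negative $D_f$ or $D_r$, a violated
incorporation target) still reject the draw; the same conditions raise
classed errors on direct calls to the user-facing operations.

Which member is sampled?  The cytosol member, when its interval is
non-degenerate; otherwise the ER member.  Structural degeneracies are
handled explicitly:

* a pair whose ER pool has no enzymatic consumer (e.g. *p*-coumarate in
  `brachy_fig4`) pins the cytosol label at $M$; only the ER enrichment
  is free;
* a pair with inflow on one side only (e.g. coniferaldehyde) forces both
  labels to the inflow enrichment, leaving the exchange unidentifiable;
  the documented fallback records the net-only resolution
  $D_f = \max(D, 0)$, $D_r = 0$;
* a pair with zero throughput gets labels 0 and zero diffusion
  components.

## Constraint screening

`check_constraints()` performs threshold screening, not likelihood
fitting: a flux/label state is admissible when every target is met within
its tolerance.  Defaults:

| target class | default tolerance | unit |
|---|---|---|
| H/G/S composition fraction | 2 | percentage points, absolute |
| S/G ratio | 10% | relative |
| label incorporation | 5 | percentage points, absolute |

The incorporation tolerance deserves a comment.  With equal precursor
inputs and a 35% feed enrichment, the total-lignin incorporations of the
two feeding experiments must sum to exactly 35% for *every* admissible
flux distribution (each unit of lignin carbon derives from exactly one
precursor).  The shipped observation table records 22.2% + 18.6% =
40.8%, so bands of $\pm 2$ points can never be satisfied jointly -- the
measurements themselves are mutually inconsistent at that precision,
presumably reflecting the difficulty of quantifying enrichment in
cell-wall hydrolysates.  A 5-point band is the smallest round tolerance
under which the table is jointly satisfiable, and it is the default;
both values are configurable per target in the constraint JSON.  For the
same reason the shipped table omits H-lignin incorporation targets
entirely: the recorded phenylalanine-feeding value (36%) exceeds the
feed enrichment itself (35%), which is physically impossible, so the
H-lignin label measurements are treated as unreliable in both feeding
experiments.

Screening is two-staged and joint across experiments
(`sample_ensemble()`): split-ratio draws are filtered on composition
first; for each survivor, label states are drawn independently for the
phenylalanine and the tyrosine experiment (default 200 tries each) and
the flux vector joins the ensemble only if at least one label draw
passes *both* experiments' incorporation targets.  Conditioning labels
on previously accepted totals (rather than re-sampling totals jointly
with labels) matches the two-step structure of the method: net steady
states first, bidirectional label resolution second.

## What a run produces

`run_pipeline()` writes the accepted total-flux ensemble and a labeled
ensemble per experiment as `#`-annotated CSV, per-member constraint
residuals, five-number summaries for every flux, both directions of
every diffusion edge, and every observable (`summarize_ensemble()`),
boxplot panels (1.5 x IQR whiskers, stated in the captions), and a JSON
manifest embedding the network, constraints and all sampler settings.
`run_from_manifest()` reproduces a run byte-identically from the
manifest alone; exit status 0 marks a non-empty ensemble, 3 an empty one
(infeasibility is a result, not an error), higher codes are errors.  The
`inst/cli/lignflux` script exposes `run`, `steady`, `label`, `synth` and
`report` subcommands over these functions.

With the shipped observation table and a 10,000-draw budget the
channel-free scheme `brachy_fig4` returns an empty ensemble while
`brachy_fig5` and `brachy_fig6` return non-empty ones whose median
observables sit near the table's model row; the acceptance script and
`tests/testthat/test-acceptance.R` recompute these quantities from
scratch.  The emptiness of `brachy_fig4` is structural, not a sampling
accident: with all inputs converging on a single cytosol *p*-coumarate
pool whose ER partner has no enzymatic consumer, every downstream pool's
enrichment is pinned to the fully mixed value (17.5% at equal inputs),
and the wall-ferulic-acid target cannot be reached at any tolerance
below 5.5 points.

## The synthetic-data generator

`generate_experiment()` stands in for unpublished raw labeling data: it
draws one admissible split-ratio vector (optionally forcing chosen
branches, e.g. a strong channel) and one feasible label state per
feeding experiment, computes exact observables, perturbs every
percentage with independent Gaussian noise (default sd 1 percentage
point, clipped to valid ranges, S/G recomputed from the noisy
fractions), and emits the result in the same constraint schema as the
shipped table.  The defaults mirror the study conditions: two feeding
experiments at 35% enrichment, inputs 100 each.

What recovery tests can and cannot show: the generator emulates
threshold-screened percentage observations with known ground truth, so
passing recovery (ensemble medians within noise of truth across seeds)
demonstrates that the sampler explores the admissible set without bias
and that the constraint machinery is calibrated.  It does not emulate
isotopologue spectra, natural-abundance background (the baseline label
of unlabeled inputs defaults to 0, as the fully labeled isotopologue has
negligible natural abundance), correlated measurement error, or
model-structure error, so agreement on synthetic data cannot validate
the biological wiring itself -- that is exactly why the scheme
comparison on the real table is the headline analysis.  Two further
caveats are deliberate: individual fluxes (notably the small channel
flux `V_8`) are not point-identifiable, so recovery is asserted on
observables, not on flux point values; and ground truths drawn near
complete pool mixing are *genuinely* indistinguishable from the
channel-free scheme -- the discrimination test therefore forces a
weak-exchange, channel-dominant truth (`pair_u` near 0), the regime the
channeling hypothesis is about.

## Numerical choices and limitations

* Tolerances: pair-balance residuals are checked to $10^{-9}$, split
  fractions must sum to 1 within $10^{-12}$; degenerate denominators are
  detected at $10^{-9}$ and fall back as described above.
* Problem sizes: the headline analyses use 10,000 split-ratio draws and
  200 label tries per survivor and experiment (seconds on one core);
  the recovery study uses 50 seeds at 5,000 draws.  These sizes give
  ensembles of order 10 members under the shipped table -- small,
  because the admissible set is a thin slice of the split-ratio cube,
  but every reported quantity is a median over members that are each
  individually admissible.
* The `r` volume-compensation constant for diffusion across compartments
  of unequal volume is parsed, validated and carried on every network,
  but inert in steady-state analyses: it would scale concentrations, not
  steady-state fluxes, and a kinetic extension is out of scope.
* Flux ids in the Brachypodium encodings are local.  The ids that the
  accompanying literature fixes by name (`V_8`, `V_22`, `V_23`, `V_24`,
  `V_28`, `D_1`...`D_10`) follow that naming; the remaining ids are
  descriptive (`V_PAL`, `V_C4H`, ...), and the full index map cannot be
  confirmed from text alone, so it is documented as provisional.
* The shikimate-ester detour (HCT, C3'H, HCT) is lumped into a single
  *p*-coumaroyl-CoA to caffeoyl-CoA edge in all three schemes.  The
  lumping is exact for both total and labeled steady-state flux: each
  ester pool pair has inflow on one side and outflow on the other only,
  which (by the degeneracy rules above) forces its labels to the
  upstream enrichment and leaves no freedom a finer encoding would add.
* The cytosolic C3H conversion of *p*-coumaric to caffeic acid is
  biochemically speculative in this organism; it is included in all
  shipped schemes (without it the wall-ferulate route would be severed
  in the channel-free scheme, making that scheme's infeasibility
  trivial), and it can be removed from a config to test the variant.
* Wall-bound ferulic and *p*-coumaric acid are modeled as dedicated
  effluxes from the cytosolic ferulate and *p*-coumarate pools; whether
  the corresponding measurements probe an efflux or a pool is an
  assumption recorded here.
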