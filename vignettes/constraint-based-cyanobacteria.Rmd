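---
title: "Constraint-based analysis of cyanobacterial metabolism with cyanoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of cyanobacterial metabolism with cyanoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoflux)
```

## The model

A genome-scale metabolic reconstruction is a stoichiometric matrix $S$
($m$ metabolites $\times$ $n$ reactions, $S_{ij}$ the coefficient of
metabolite $i$ in reaction $j$) with per-reaction flux bounds and Boolean
gene--protein--reaction (GPR) rules. Flux balance analysis (FBA) treats
growth as a linear program:

$$\max_v \; v_{\mathrm{biomass}} \quad \text{s.t.} \quad S v = 0,\;\;
v_{j,\min} \le v_j \le v_{j,\max},$$

where the biomass reaction drains precursors in experimentally measured
proportions and its flux is the growth proxy. The steady-state constraint
encodes that no internal metabolite accumulates; exchange
pseudo-reactions carry material across the system boundary, with uptake
as negative flux by the usual COBRA sign convention. Because the optimal
flux vector is almost never unique in genome-scale models, any single FBA
solution is reported as *one optimal vertex*; statements about individual
reactions use flux variability analysis (FVA), which minimises and
maximises each reaction's flux subject to the same constraints plus a
floor on biomass:

$$\min / \max \; v_j \quad \text{s.t.} \quad S v = 0,\; v \in [v_{\min},
v_{\max}],\; v_{\mathrm{biomass}} \ge v_{\mathrm{bio}}^{\min}.$$

The floor defaults to 100% of the scenario optimum
(`floor_fraction = 1`), the convention used when comparing predicted
ranges against $^{13}$C labelling flux measurements taken under
near-maximal growth; it is configurable for sub-optimal analyses.

## Diurnal constraints

Cyanobacteria such as *Cyanothece* partition their metabolism over the
day: in the light they fix CO$_2$ photosynthetically and store glycogen,
in the dark they burn the stored carbon (and, in diazotrophs, fix
nitrogen, co-producing H$_2$ via nitrogenase). `cyanoflux` represents a
phase as bound modifications applied by `apply_diurnal()` over four named
reaction sets (every listed transport written uptake-positive):

* **light** — stored-carbon uptake (glycogen/glycerol transport) is
  clamped to zero; light and carbon-fixation reactions stay free;
* **dark** — light reactions and carbon-fixation reactions are clamped to
  zero and CO$_2$ uptake is disabled ($v_{\mathrm{CO2tr}} \le 0$, release
  still allowed), while stored carbon may be consumed;
* **subjective dark** — the dark constraints with the light reactions
  left active: stored glycogen is the carbon source while light energy is
  still harvested, the condition under which nitrogenase-driven H$_2$
  yields are measured.

The exact inequality forms behind the light/dark switch were an open
design point; we chose hard zero-clamps on the phase-forbidden transports
because they make the phase semantics checkable as invariants (dark
optima provably carry zero carbon-fixation and photon flux) and because
separate light/dark biomass equations, not soft bounds, carry the
physiological asymmetry. Condition-specific regulatory knowledge that is
not a phase (for example an aerobic-only enzyme system) belongs in a
scenario's `shutdown` list, not in the GPRs.

## GPR logic and knockouts

GPR rules are parsed into AND/OR trees over gene identifiers, with AND
binding tighter than OR (the source models do not state a precedence; we
follow the COBRA convention). Complexes (AND) die with any subunit;
isozymes (OR) need all members lost. The distinguished leaf `unknown`
represents the "unknown gene" device used during curation when a
reaction demonstrably proceeds although no annotated gene fully accounts
for it: it is always satisfiable and no knockout can remove it, so a rule
`g or unknown` makes `g` dispensable by construction. Gene ids are
compared case-sensitively after trimming, as cyanobacterial locus tags
are case-stable. A knockout maps to the reaction set whose rules
evaluate false, and those reactions' bounds are pinned to $[0,0]$
(`apply_knockout()`).

The essentiality screen (`single_gene_deletions()`) calls a deletion
viable when the mutant optimum reaches at least `threshold_fraction`
(default 10%) of the wild-type optimum of the same scenario. Joined to
in vivo viability the four outcomes are GG, GNG, NGG, NGNG (first letter
pair in silico, second in vivo), with specificity
$\mathrm{GG}/(\mathrm{GG}+\mathrm{NGG})$ and sensitivity
$\mathrm{NGNG}/(\mathrm{NGNG}+\mathrm{GNG})$; a zero denominator yields
`NA` rather than 0. Mutants with incompletely segregated chromosome
copies carry no reliable information and are dropped when reading
viability tables.

## Quality control

**Balance linting.** For every metabolic and transport reaction whose
participants all have a parseable Hill formula and a charge, the checker
sums coefficient $\times$ element count (and charge) and flags any
nonzero net. Exchanges and biomass reactions are net
producers/consumers by design and are skipped, as are reactions touching
metabolites with unknown composition — each skip is reported with its
reason so gaps in annotation stay visible.

**Blocked metabolites.** A metabolite is blocked when no steady-state
flux distribution under the scenario's exchanges produces it. We decide
this with plain LPs: a metabolite is producible iff some incident
reaction's flux range (computed once for all reactions, no biomass
floor) runs in the producing direction. This reproduces the classic
binary-variable connectivity formulation without integer programming: a
dead end with producers but no consumers is blocked because mass balance
forces its producers to zero, and blockage propagates to everything
exclusively downstream. Note the corollary used throughout the tests:
severing one step of a linear pathway blocks *every* metabolite on the
pathway, not just the directly orphaned one.

**Gap filling.** `propose_gapfill()` searches a user-supplied universal
reaction pool for minimal-cardinality addition sets that unblock a
target, by iterative deepening over subset size; ties are returned in
lexicographic id order so reports are reproducible. The literature
corroboration step that decides whether a proposal is *believed* is
inherently manual and out of scope; its mechanical counterpart —
rejecting proposals that create thermodynamically infeasible cycles — is
`filter_proposals_by_loops()`, which rejects a proposal iff applying it
strictly enlarges the loop-member set.

**Infeasible loops.** With every exchange closed, any internal reaction
still able to carry flux at the big-M scale participates in a cycle with
zero net exchange — flux that would be unbounded were bounds infinite,
and thermodynamically impossible in a closed system. The detector flags
reactions whose closed-exchange flux range exceeds
`threshold_fraction` (default 0.5) of the largest internal bound
magnitude, so the report is invariant under rescaling all bounds, and
groups members by the shared support of witness flux vectors (each
witness satisfies $Sv = 0$, $v \neq 0$, zero exchange flux).
Direction-restriction repairs (making one duplicate irreversible) are
suggested by the witnesses but never auto-applied.

## The linear programming layer

No dedicated LP package is available in this package's dependency
footprint, so `cyanoflux` carries a dense two-phase primal simplex over
bounded variables with Bland's anti-cycling rule (`R/lp.R`): inequality
side-constraints (e.g. a shared substrate basis such as "100 mmol CO$_2$
plus bicarbonate, jointly") get slack variables, phase 1 drives
artificial variables to zero, and phase 2 optimises with the artificials
pinned. Problems here are tens of reactions, so the basis inverse is
recomputed per pivot — simplicity over speed. Infinite bounds are
normalised to $\pm 1000$ flux units at model construction (the
conventional big-M for genome-scale models; configurable), which keeps
every LP bounded and turns "unbounded flux" into "flux at the big-M
scale", exactly the signal the loop detector uses.

Correctness is established by two independent routes rather than trust:
an exhaustive basic-solution enumerator (`brute_force_fba()` /
`brute_force_fva()`, sharing no code with the simplex) must agree to
$10^{-6}$ on every generated network of at most 8 reactions, and the
COBRA toolchain, reading our SBML output, must reproduce optima on the
fixtures. Solver tolerances are surfaced, not hidden: every returned
flux distribution carries its steady-state residual ($|Sv|_\infty$,
warned above $10^{-6}$), bounds are respected to $10^{-9}$, and
producibility/blockage decisions use a $10^{-6}$ flux threshold. The
FVA floor is relaxed by a relative $10^{-9}$ when imposed, so that
fixing an objective at its own optimum never manufactures infeasibility
from round-off.

## The synthetic study system

`make_mini_phototroph()` builds a 21-reaction, 15-metabolite
cyanobacterium in miniature: photon/CO$_2$/O$_2$/water/glycogen/H$_2$
exchanges, photon-driven ATP synthesis, an oxidative NADPH route (3
NADPH per one-carbon unit oxidised, the pentose-phosphate role), carbon
fixation (1 CO$_2$ + 2 NADPH + 3 ATP per CH$_2$O unit), glycogen
synthesis and mobilisation, respiration (4 ATP per unit), a
nitrogenase-style H$_2$ reaction (2 NADPH + 4 ATP per H$_2$), and
separate light and dark biomass equations. Carbon-carrying metabolites
have real formulas so the balance checker has substance to check;
photons and the ATP/NADPH tokens deliberately have none, exercising the
"skipped with reason" path. Its GPRs plant one essential
carbon-fixation gene, an essential transporter, a two-gene AND complex,
an OR isozyme pair and an `unknown`-rescued gene.

All headline numbers are derived by hand from the stoichiometry and
stored as ground truth: light biomass equals CO$_2$ uptake/10 (carbon
is limiting; photons are not), carbon fixation runs at $\ge 35$ per
unit biomass, dark biomass equals $8G/19$ at glycogen uptake $G$ (six
carbon units per glycogen, 8 for structure and 25/4 burned for ATP),
and subjective-dark H$_2$ equals $9G$ (18 NADPH from fully oxidising
six carbons, at 2 NADPH per H$_2$, ATP photon-supplied). Default uptakes
are 10 mmol CO$_2$ (light) and 5 mmol glycogen (dark) — small round
numbers in the conventional mmol gDW$^{-1}$ h$^{-1}$ scale that keep
every analytic optimum an exact rational.

What the generator does *not* emulate: genome-scale size (hundreds to
thousands of reactions), compartment-specific proton bookkeeping,
photorespiration and photon-per-photosystem accounting, cofactor
promiscuity, and measured biomass compositions. Passing tests therefore
demonstrate algorithmic correctness on networks whose answers are
provable, not biological fidelity of any particular reconstruction;
applying the pipeline to a published SBML reconstruction exercises
exactly the same code paths (`read_sbml()` accepts Level 3 + fbc and
legacy Level 2 bound/notes encodings; which encoding a given
supplementary file uses cannot be assumed, so the reader probes both).

`plant_defect()` injects exactly one known flaw — a reversed duplicate
reaction (a forced two-cycle), a deleted sole consumer (an orphaned
metabolite), or a one-hydrogen formula perturbation placed so that
exactly one checkable reaction breaks — and records the affected ids,
giving the QC detectors planted oracles with precision and recall
exactly 1 to aim for. Defect sites are chosen from a seeded, locally
scoped random stream; the same seed reproduces the same model bit for
bit and never disturbs the caller's RNG.

## Problem sizes and numerical choices

The shipped analyses and tests run FBA/FVA on networks of 5--26
reactions, oracle comparisons on 3--8 reactions (where exhaustive
enumeration of basic solutions is exact and fast), 54 defect-planted
fixtures, and full truth tables for GPRs of up to 6 genes ($2^6$
knockout subsets per rule). These sizes make every expectation either
analytic or exhaustively enumerable; nothing in the design caps the
size the machinery accepts, and the per-LP cost grows as a small
polynomial in reaction count.

Remaining limitations: alternate optima make any single flux vector
arbitrary (use FVA); the loop detector reports cycle *membership*, not a
minimal cycle basis; gap-fill search is exhaustive over subsets and so
meant for small candidate pools (its MILP formulation would scale
further); and thermodynamic ($\Delta G$-based) constraints are out of
scope — loop removal here is purely structural.
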