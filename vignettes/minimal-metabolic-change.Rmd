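---
title: "Quantifying the minimal metabolic change behind cross-feeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the minimal metabolic change behind cross-feeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeedr)
```

## The question and the model

When a clonal bacterial population grows in a glucose-limited chemostat,
it can diversify into a *producer* strain that excretes a secondary
carbon source and a *consumer* strain that feeds on it. Whether a given
metabolite is a plausible basis for such a cross-feeding pair can be
screened computationally: the fewer reactions that must change their
flux for producer and consumer phenotypes to exist, the more accessible
the interaction is to evolution. This package computes those minimal
flux-change counts ("metabolic distances") on any stoichiometric model.

All computations live on the steady-state flux polytope

$$\{v \in \mathbb{R}^r : S v = 0,\; l \le v \le u\}$$

with $S$ the $m \times r$ stoichiometric matrix. The chemostat
environment enters through exchange-reaction bounds: the dilution rate
$D$ fixes growth ($v_{growth} = D$, an equality, since at steady state
the population grows exactly as fast as it is washed out), the limiting
carbon source is capped for uptake, non-limiting inorganic nutrients are
open, and every other exchange is closed for uptake. Negative exchange
flux is uptake, positive is secretion.

## The ancestral state

The ancestor is modeled by parsimonious FBA: among all flux vectors
achieving $v_{growth} = D$, take one minimizing $\sum_i |v_i|$, a proxy
for total enzyme expression. Absolute values are realized by splitting
each flux into non-negative forward and reverse parts inside the solver;
the objective value (total flux) and constraint satisfaction are the
contract, while individual fluxes of a degenerate optimum are advisory.
On the bundled fixture the parsimonious ancestor fully oxidizes its
substrate and excretes no by-product — the same qualitative behavior a
genome-scale *E. coli* model shows in a glucose-limited chemostat.

## Strain constraint sets

* **Producer**: growth $= D$; excretion of the secondary metabolite
  fixed at 1 mmol gDW$^{-1}$ h$^{-1}$ (a small, arbitrary but fixed
  commitment to production); glucose uptake fixed at the *minimal* value
  for which that excretion and growth are jointly feasible. The
  minimization mirrors the fact that a chemostat resident cannot afford
  gratuitous substrate consumption; the producer typically needs
  *more* glucose than the ancestor because the excreted carbon must come
  from somewhere.
* **Consumer**: growth $= D$; glucose uptake disallowed entirely (the
  clean way to isolate the changes tied to switching carbon source);
  uptake of the secondary metabolite fixed at its minimal feasible
  value. Fixing the consumer's uptake at the minimized value is a
  symmetry choice, mirroring the producer's glucose treatment. A
  variant role (`consumer_with_glucose`) instead fixes glucose uptake at
  1 mmol gDW$^{-1}$ h$^{-1}$ alongside the secondary source.
* **Heterogeneous ancestor**: growth $= D$ and glucose uptake *bounded
  above* by a cap (not fixed), so the ancestor may be any flux
  distribution the environment admits.

Metabolites whose consumer problem is infeasible (they cannot serve as a
sole carbon source) are excluded from scans and reported, not errors.

## Flux-change minimization

Given the ancestral reference $a$, ROOM counts the internal reactions
whose flux must leave the band $[a_i - \beta,\, a_i + \beta]$ for the
evolved constraint set to be satisfiable, by solving a MILP with one
binary indicator per counted reaction. The two indicator inequalities
are written exactly with the model bounds as implicit big-M constants,
so any MILP solver could take the formulation unchanged. Only internal
reactions enter the objective; exchange and biomass fluxes are
constrained but never counted.

The joint variant (`room_het`) drops the fixed reference: it finds an
ancestral distribution $a$ (in the ancestor's constraint set) and an
evolved distribution $e$ (in the evolved set) *simultaneously*,
minimizing the count of internal reactions with $|e_i - a_i| > \beta$.
This models a phenotypically heterogeneous ancestral population — the
member of the ancestral flux space closest to the evolved strain is the
relevant starting point. Written with both $a$ and $e$ as variables the
indicator inequalities contain products of $f_i$ with $a_i$; the package
uses the standard big-M linearization
$|e_i - a_i| \le \beta + f_i M_i$ with $M_i$ derived from the box
bounds, which has exactly the intended semantics at every integer $f$.
By construction the joint optimum can never exceed the fixed-reference
distance when the reference lies in the ancestor's set (the reference is
a feasible choice of $a$); this dominance is asserted in tests.

MoMA (minimization of squared Euclidean adjustment, a quadratic program)
is included as the standard comparison method; it generally changes more
reactions than the ROOM count because its objective does not penalize
the number of changed reactions.

### Classification

Changed reactions ($|e_i - a_i| > \beta$) are partitioned into *turned
on* (inactive in the ancestor, active in the evolved strain), *turned
off* (the reverse), and *magnitude change* (active in both), with
activity meaning $|v| > 0.001$ mmol gDW$^{-1}$ h$^{-1}$. A reaction
changed but inactive on both sides (possible only marginally when the
two thresholds interact) is filed under magnitude change so the three
classes always partition the changed set.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `dilution_rate` | 0.2 | h$^{-1}$ | chemostat growth rate, imposed as an equality |
| `uptake_cap` | 10 | mmol gDW$^{-1}$ h$^{-1}$ | primary-carbon uptake limit for plain FBA/pFBA |
| `beta` | 0.001 | mmol gDW$^{-1}$ h$^{-1}$ | flux change considered substantial |
| `excretion_rate` | 1 | mmol gDW$^{-1}$ h$^{-1}$ | producer's imposed excretion |
| `activity_threshold` | 0.001 | mmol gDW$^{-1}$ h$^{-1}$ | active/inactive cutoff for classification |

Distances are non-increasing in $\beta$ (a wider band is easier to stay
inside); the suite checks $\beta \in \{0.0002, 0.001, 0.005\}$ and the
fixture distances move by at most two counts across that 25-fold range.

## Numerical design

No linear or mixed-integer solver package is available to this package
as a dependency, so it carries its own optimization core:

* a dense two-phase primal simplex with bounded variables (C++), used
  for every LP; bounds beyond $10^6$ in magnitude are treated as
  infinite, and an optimum pinned to such a clamped bound is reported as
  unboundedness with a witness column;
* a depth-first branch-and-bound layer for the indicator MILPs. The
  objective is a count, so node bounds are rounded up to the next
  integer for pruning; the 0-branch (reaction unchanged) is explored
  first; the search starts from a feasible incumbent built by taking any
  evolved-feasible flux vector and declaring changed whatever deviates
  from the reference. Exhausting the node budget raises an error
  carrying the best proven bound — never a silently suboptimal answer;
* indicators are rounded post-solve and the indicator constraints
  re-verified at $10^{-6}$;
* the MoMA quadratic program is delegated to a dual active-set QP
  routine, with dependent equality rows removed by QR beforehand;
* LP optimality/feasibility tolerances are $10^{-9}$ requested and
  $10^{-6}$ asserted on every returned distribution ($|S v| \le 10^{-6}$
  and bounds within $10^{-6}$), so the count-based classification
  downstream sees clean near-zeros.

Degenerate alternate optima are a fact of flux analysis: the *distance*
(objective value) is the deterministic contract, while the identity of
the changed reactions is reported as one optimal solution among possibly
many. Overlap statistics across strains (`shared_reactions`) carry an
explicit caveat for the same reason. Rank ties in metabolite rankings
share the minimum rank (competition ranking), a convention recorded in
the output.

## What the synthetic networks emulate — and what they do not

`make_core_fixture()` is a deterministic 17-reaction network shaped like
a cartoon of central carbon metabolism: lumped glycolysis feeding
pyruvate and ATP, a high-ATP-yield oxidative lump, a low-yield overflow
branch excreting an acetate-like by-product, an assimilation route for
that by-product, a second glycerol-like by-product with synthesis and
catabolic routes, two biomass precursors, and an ATP-maintenance sink.
Its yields were chosen at design time so that (i) the parsimonious
ancestor strictly prefers full oxidation (no overflow), and (ii) the
acetate-like producer is reachable by rerouting exactly four internal
reactions at its minimal glucose uptake — a property the
subset-enumeration oracle verifies rather than assumes. The random
generator (`make_toy_network`) builds a feasible backbone chain first
and decorates it, so growth feasibility is guaranteed by construction
and every generated model is exhaustively checkable.

These toys reproduce the *structure* of the scientific problem (steady
state, uptake caps, overflow vs. oxidation, by-product import) at a
scale where brute force is possible. They do not reproduce genome-scale
degeneracy — thousands of reactions, parallel isozymes, cofactor
cycles — so passing desk tests demonstrates correctness of the
optimization machinery, not numerical performance or biological
conclusions at genome scale. The genome-scale runner
(`ijo1366_reproduction`) exists for that purpose and requires a locally
downloaded copy of the iJO1366 reconstruction; with the package's own
branch-and-bound it is an overnight computation, not a test-suite item.

The problem sizes used by the test suite and the acceptance script —
toy networks of four to eight backbone reactions, twenty seeded
networks for the oracle comparison, $10^5$ Monte-Carlo replicates,
exhaustive Fisher-table enumeration to a grand total of 30 — were
chosen so the whole desk suite completes in well under two minutes on a
single core while still exercising every code path exhaustively.

## The sequential-emergence model

Ranking by total distance treats producer and consumer evolution as
independent, but the consumer cannot establish before the producer
exists. The package's two-stage model makes the minimal set of
assumptions: per generation, a producer establishes with probability
$p_P = e^{-\lambda d_P}$; once established, the consumer follows with
per-generation probability $p_C = e^{-\lambda d_C}$. Both waiting times
are geometric, and the probability that the pair exists by generation
$T$ has the closed form

$$P(T) = 1 - \frac{p_C (1-p_P)^T - p_P (1-p_C)^T}{p_C - p_P}
\qquad (p_P \ne p_C),$$

with the $p_P = p_C$ limit handled separately. This parametric form is
an explicit reconstruction — exponential decay of establishment
probability with metabolic distance is an assumption, not a derived
result — and $\lambda$ is user-settable; the default
$\lambda = \ln(100)/57$ gives a median-scale producer distance an
establishment probability of $10^{-2}$ per generation. The closed form
is verified against Monte-Carlo simulation, and across realistic
distance spreads the model's ranking agrees with the simple
total-distance proxy (|Spearman| well above 0.9), which is exactly why
the cheaper proxy is a reasonable screen.

## Design choices that were genuinely open

* **Growth as equality.** The evolved strains' growth is fixed at $D$
  rather than $\ge D$, matching the steady-state logic that fixes the
  ancestor's growth.
* **Consumer uptake minimized.** Nothing forces the consumer's
  secondary uptake to its minimum; fixing it there mirrors the
  producer's glucose treatment and keeps the two roles symmetric. The
  choice is recorded in each result's provenance.
* **Maintenance bounds untouched.** Environment construction rewrites
  only exchange bounds; ATP-maintenance-style internal demands keep
  their model defaults.
* **Exchange-role detection.** A single-metabolite column on an
  extracellular species is an exchange; single-metabolite columns on
  internal species (maintenance/demand pseudo-reactions) stay internal
  and are flagged explicitly, so they are counted like any other
  internal reaction.
* **Reversible fluxes on the net scale.** The change indicators compare
  net fluxes $e_i - a_i$; splitting into forward/reverse parts happens
  only inside the pFBA objective, never in the distance.

## Known limitations

* Branch-and-bound with a dense simplex scales to toy networks and
  (slowly) to genome scale; there is no presolve, cut generation or
  warm-starting across nodes.
* Changed-reaction identities, and therefore gene/operon/regulon counts
  derived from them, inherit MILP optimum non-uniqueness.
* The gene-direction prediction rule (per-reaction flux-magnitude
  votes, majority per gene, ties to unchanged) is an artifact decision;
  other defensible rules exist.
* The sequential-emergence module is a labeled approximation, not a
  calibrated population-genetic model.
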