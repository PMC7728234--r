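# crossfeedr

Constraint-based analysis of how much metabolic change a glucose-limited
ancestral bacterium needs before it can split into a cross-feeding pair: a
*producer* strain that excretes a secondary carbon source and a *consumer*
strain that lives on it. The package quantifies, for each candidate
cross-fed metabolite, the minimal number of reactions whose flux must
change for each strain to exist — a parsimony proxy for how likely that
cross-feeding interaction is to evolve in a chemostat.

## Who this is for

Microbial systems biologists and evolution modelers working with
genome-scale metabolic reconstructions (SBML-FBC or BiGG JSON) who want
flux-rearrangement distances between an ancestral flux state and
constrained "evolved" flux spaces, with exact, solver-verified optima on
models small enough to check by enumeration.

## The core computation

All methods share the steady-state flux polytope
`{v : S v = 0, l <= v <= u}` where `S` is the m x r stoichiometric matrix.

- **FBA** — maximize `v_growth` over the polytope.
- **pFBA** — among flux vectors with `v_growth = D` (the chemostat
  dilution rate), minimize `sum_i |v_i|`; this defines the ancestral flux
  distribution `a`.
- **ROOM** — given `a` and the evolved strain's constraint set, solve the
  mixed-integer program

  ```
  min  sum_i f_i          (f_i binary, i over internal reactions)
  s.t. S e = 0,  l^e <= e <= u^e
       e_i - f_i (u_i - (a_i + beta)) <= a_i + beta
       e_i - f_i (l_i - (a_i - beta)) >= a_i - beta
  ```

  so `f_i = 0` forces `|e_i - a_i| <= beta` and the optimum counts the
  reactions that must change by more than `beta` (default 0.001
  mmol gDW^-1 h^-1).
- **Joint variant** (`room_het`) — for a phenotypically heterogeneous
  ancestral population: find `a` and `e` *simultaneously*, each in its own
  constraint set, minimizing the number of internal reactions with
  `|e_i - a_i| > beta`.
- **MoMA** — minimize `sum_i (e_i - a_i)^2` (quadratic program), as a
  comparison method.

Producer constraints: growth fixed at `D`, secondary-metabolite excretion
fixed (default 1 mmol gDW^-1 h^-1), glucose fixed at the minimal uptake
that keeps the problem feasible. Consumer constraints: growth fixed at
`D`, glucose uptake disallowed, secondary uptake fixed at its minimal
feasible value. Ranking metabolites by producer + consumer distance
orders candidate cross-feeding interactions by evolutionary
accessibility, and a glucose-uptake sweep shows how the distances shrink
when the ancestor may consume more than the minimal glucose.

Because no LP/MILP solver package is available as a dependency, the
package ships its own dense bounded-variable simplex (C++) and a
branch-and-bound layer, plus an exhaustive subset-enumeration oracle that
re-derives every MILP optimum independently on the bundled toy networks.

## Worked example

```r
library(crossfeedr)

model <- make_core_fixture()       # bundled 17-reaction toy network
env   <- core_fixture_env()        # D = 0.2 h^-1, glucose-limited

anc <- ancestral_state(model, env) # parsimonious ancestor
-anc$values[["EX_glc_e"]]
#> [1] 0.7333333                    # glucose uptake, mmol gDW^-1 h^-1
anc$values[["EX_ace_e"]]
#> [1] 0                            # no by-product excretion

res <- compute_distances(model, env, c("EX_ace_e", "EX_glyc_e"),
                         method = "room")
rank_metabolites(res)
#>   metabolite producer consumer total rank
#> 1  EX_glyc_e        3        4     7    1
#> 2   EX_ace_e        4        4     8    2
```

Four reactions must change flux for the acetate-like producer to exist
(the overflow branch and its transporter turn on, the oxidative lump
turns off, and glucose uptake rises), four for its consumer; the
glycerol-like by-product is one reaction closer and therefore ranks
first. `glucose_sweep()` shows the producer distances dropping to zero
once the ancestor may consume as much glucose as the producer needs.

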