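---
title: "Context-specific metabolic models and flux sampling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific metabolic models and flux sampling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(contextflux)
```

# Scope

`contextflux` analyses how perturbations (for example, toxin exposures
that silence particular genes) reshape the usable part of a
compartmentalised metabolic network. The workflow is: threshold
transcriptomic measurements into present/absent and up/down calls;
extract a context-specific sub-model consistent with each condition's
expression state; sample the steady-state flux space of each sub-model;
and compare conditions through correlated reaction sets, differential
reaction fluxes and compartment profiles. This vignette documents the
underlying model, every default parameter and the main numerical and
design decisions. The worked examples in the package README show actual
numbers; here the focus is on *why* each stage is built the way it is.

# The constraint-based model

A metabolic network is a set of metabolites (each assigned to one
compartment: cytosol `c`, extracellular `e`, Golgi `g`, lysosome `l`,
mitochondria `m`, nucleus `n`, endoplasmic reticulum `r`, peroxisome
`p`), a set of reactions with finite flux bounds, a sparse
stoichiometry map, and boolean gene–protein–reaction (GPR) rules over a
gene universe. The steady-state assumption is

$$ S v = 0,\qquad lb \le v \le ub, $$

where $S$ is the stoichiometric matrix (metabolites × reactions) and
$v$ the flux vector. Flux balance analysis (FBA) maximises (or
minimises) the flux of an objective reaction — by convention a biomass
or functionality sink — over this polytope.

Conventions baked into the data model:

* **Exchange reactions** consume a single extracellular metabolite with
  coefficient −1; uptake is a *negative* exchange flux. "Rich media" is
  modelled by opening every exchange lower bound to `-uptake`
  (default magnitude 1000, the conventional "effectively unbounded"
  flux unit in constraint-based models).
* **GPR rules** are `and`/`or` trees over gene identifiers. An empty
  rule means the reaction is not gene-associated and always available.
* **Bounds are finite.** Infinite bounds make the sampling polytope
  unbounded and hide modelling mistakes; the validator rejects them.
* The **null-space dimension** of $S$ (numerical rank via SVD with the
  standard tolerance `max(dim) * eps * max(singular value)`) counts the
  independent steady-state degrees of freedom and is the first sanity
  check after loading or generating a network.

Networks round-trip through a canonical JSON dialect (byte-identical on
re-write, used for fixtures and artefacts) and through SBML Level 3
with the FBC version 2 extension for interoperability.

# Expression thresholds

* **Presence**: a gene is present when its intensity is at or above the
  cutoff, default **11** intensity units, boundary inclusive. The
  cutoff is a property of the normalised intensity scale the calls were
  designed for and should be re-derived when porting to another
  platform.
* **Differential expression**: up-regulated when the linear fold change
  is strictly above **1.75**, down-regulated strictly below **0.55**,
  both gated by `p <= 0.05` and FDR `q < 0.1`. The near-symmetric pair
  (1/1.75 ≈ 0.571) reflects common microarray practice of thresholding
  at ±0.8 on the log2 scale and then rounding on the linear scale.
* Multi-condition structure is summarised by the generalised Venn
  partition: the union of the per-condition sets split into the
  $2^k-1$ occupancy strata. Fold-change distributions across
  conditions are compared with the Kruskal–Wallis rank test (delegated
  to `stats::kruskal.test`) and Dunn's tie-corrected post-hoc $z$
  comparisons with Bonferroni adjustment. Dunn's test is implemented in
  the package because no dependency in the allowed stack provides it;
  the implementation is property-tested against a from-first-principles
  oracle.

# Context extraction (GIMME)

Given presence calls, reactions whose GPR evaluates false are *absent*
and receive penalty 1; all others receive penalty 0. The extraction LP
minimises total penalised absolute flux subject to steady state,
bounds, and a functionality floor: the objective must attain at least a
**required fraction 0.5** of the parent model's FBA optimum. Absolute
values are handled by the standard forward/backward split
($v = v_f - v_b$, both non-negative). The extracted sub-model keeps
every penalty-0 reaction plus any absent reaction that still carries
flux above the activity tolerance (1e-9) — those are the
*inconsistencies*, and their total penalised flux is the inconsistency
score. The sub-model is re-verified by FBA: the floor must still be
attainable inside the extracted reaction set.

**Consensus over reaction reorderings.** The extraction LP is usually
degenerate: parallel routes can carry the floor interchangeably, and
which route a deterministic simplex picks depends on the column order.
Rather than hide this, the extractor is run **3** times (default) on
seeded random permutations of the reaction columns and the retained
sets are intersected. The consensus keeps only order-independent
reactions. When the intersection no longer supports the functionality
floor — which happens exactly when the floor *must* flow through one of
several interchangeable absent routes — the consensus is flagged
infeasible with a classed warning rather than silently patched, because
at that point the data genuinely cannot decide between the routes.

# Sampling the flux polytope (ACHR)

Artificially-centred hit-and-run sampling:

1. **Warm-up**: flux-variability corners — FBA minimum and maximum for
   every reaction, deduplicated. These span the polytope.
2. Each step picks a random previously seen point (warm-up or
   accepted), forms the direction from the running centre through it,
   and moves to a uniformly chosen point on the feasible chord.
3. The running centre is the mean of all points seen so far, which
   increasingly aligns proposals with the polytope's long axes.

Numerical decisions:

* Every candidate direction is **projected onto an orthonormal
  null-space basis of $S$** (computed once per run by SVD) before
  normalisation. Differences of nearly coincident feasible points are
  dominated by floating-point noise with components *outside* the null
  space; normalising and stepping along them walks the chain off the
  steady-state manifold, and the error compounds. With the projection,
  $\|Sv\|_\infty$ stays at machine precision over thousands of steps,
  and feasibility checks use an honest 1e-6 tolerance.
* Default **5000 points** per model; on a uniform 1-D polytope this
  puts the Monte-Carlo standard error of a mean flux at about 0.4 % of
  the flux range, small enough for fold-2 differential calls.
* Per-condition samples are produced for *each* consensus iteration's
  sub-model and **merged** (intersection of reaction columns,
  concatenated rows), so downstream statistics average over the solver
  degeneracy instead of conditioning on one arbitrary extraction.
* After merging, magnitudes strictly below the **numerical cutoff
  1e-7** are set to exactly 0, so "off" reactions have genuinely
  constant zero columns instead of noise-scale jitter.

# Correlated reaction sets (co-sets)

Reactions whose sampled fluxes move together act as one functional
unit. Co-sets are the connected components of the graph that links two
reactions when their Pearson correlation satisfies $|r| \ge 0.975$
(single linkage; a complete-linkage clique variant is available for
small inputs). Anticorrelation counts as coupling by default because a
reversible reaction written in the opposite direction is still the same
pathway unit; a `signed` mode restricts to positive correlation.
Constant columns (zero variance, e.g. cutoff-zeroed reactions) are
excluded before correlation. Co-sets with at least **6** members are
reported as "large"; for these, a representative reaction (largest mean
absolute control flux, present in every condition) is profiled as the
percentage split of its mean absolute flux across conditions, and
profiles are clustered with average-linkage hierarchical clustering on
Euclidean distance.

# Differential reaction flux

For each reaction shared by a treated and a control sample matrix,
three filters must all pass:

1. **Welch's t-test** (or a paired test on per-index differences) with
   **Bonferroni** correction at family level **α = 0.05** over the
   reactions actually tested (zero-variance-in-both reactions are not
   tested and do not count toward the family).
2. **Fold ≥ 2** between the *absolute* mean fluxes, symmetric in
   direction (max of ratio and inverse ratio); means below 1e-7 are
   treated as exact zeros, activation from zero is an infinite fold.
3. **Magnitude ceiling 1000**: reactions whose mean rides an artificial
   bound in either condition carry no biological contrast and are
   excluded.

The t-test is appropriate here because, at thousands of sampled points,
the sampling distribution of a mean flux is very close to normal; the
Bonferroni family is kept small by the preceding extraction and cutoff
stages.

# Protein demand

A demand for a specific protein is modelled as a sink reaction
consuming the cytosolic amino-acid metabolites of the protein's residue
counts. During context extraction the demand's lower bound is set to a
small forced flux (**1e-6**) so the extraction cannot simply switch the
demand off; before sampling the bound is released to 0 so the sampled
distributions are not conditioned on an arbitrary forced value.
Sequences are read from FASTA via `Biostrings`.

# The LP solver

All stages reduce to linear programs with equality constraints and
finite variable bounds. The package ships its own two-phase
bounded-variable primal simplex with **Bland's smallest-index rule**.
This was a deliberate build decision: of the LP implementations in the
allowed dependency stack, none handled equality-constrained problems
with negative lower bounds and degenerate feasible sets reliably, and
one used randomised pivoting, which breaks the hard requirement that
every stage be a pure function of (inputs, config, seed). Bland's rule
is slower than steepest-edge pricing but immune to cycling and fully
deterministic, which is what the reordering-consensus design measures
against. The solver is validated in the test suite against an
independent implementation on randomly generated feasible problems and
against closed-form bottleneck optima on generated pathway networks.

# Synthetic data with planted ground truth

The generators exist to make every pipeline claim checkable:

* `make_toy_network()` builds independent linear pathway chains
  (exchange → transport → conversions → sink). Every unbranched chain
  is a planted fully-coupled set and contributes exactly one null-space
  dimension; a *bypass* (parallel duplicate of one conversion) breaks
  the coupling at that step and adds one dimension. FBA optima equal
  the chain bottleneck capacity in closed form.
* `make_expression()` plants exact presence/absence calls (clamped
  log-normal intensities on either side of the cutoff) while keeping
  seed-dependent noise in the intensities themselves.
* `make_de_tables()` plants an exact Venn occupancy partition at any
  scale, plus optional per-condition log-scale fold shifts that give
  the rank test a known location effect.
* `synthetic_study()` bundles one coherent multi-condition study: three
  chains, one toxin silencing a bypassed gene (the network can adapt),
  one silencing an unbypassed gene (its chain is blocked), one
  silencing nothing.

What the generators deliberately do **not** emulate: genome-scale
network topology (loops, cofactor coupling, promiscuous enzymes),
realistic transcript-to-flux noise, or the scale of real
reconstructions. Chains make ground truth exact; conclusions about
statistical behaviour on real networks require real networks. Problem
sizes used in the tests (chains of 3–6 metabolites, up to ~30
reactions, thousands of sampled points) are the package's own choice:
large enough for the asymptotic statistics to apply, small enough that
oracles stay brute-forceable.

# Reproducibility

One master integer seed drives everything. Stage seeds are derived as
`derive_seed(master, stage, index)` (a documented affine map modulo
2^31 − 1), the RNG state is saved and restored around every seeded
computation, and all tabular artefacts are written with stable row and
column ordering — so re-running `run_pipeline()` with the same
configuration produces byte-identical files, and the emitted
`manifest.json` (package version, parameter echo, stage seeds, artefact
list) suffices to reproduce any artefact.

# Limitations

* The simplex implementation is dense and suitable for desk-scale
  networks (hundreds of reactions), not genome-scale reconstructions;
  the algorithms are scale-independent but the solver is the
  bottleneck.
* Co-set detection from finite samples is a statistical estimate; at
  the default threshold, weakly coupled reactions near $|r| = 0.975$
  can flip membership between sample sizes.
* The consensus mechanism characterises solver degeneracy under column
  reorderings only; other sources of alternate optima (bound
  perturbations) are out of scope.
* Presence and DE thresholds are platform-bound constants, not
  estimated from the data.
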