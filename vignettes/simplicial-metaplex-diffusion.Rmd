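---
title: "Diffusion on simplicial metaplexes: model, discretization and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion on simplicial metaplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaplexr)
```

## Two models of diffusion on a simplicial complex

A simplicial complex assigns geometry to group interactions: vertices,
edges, filled triangles, closed under faces. `metaplexr` implements two ways
of running diffusion on one, built from the same combinatorial object so
they can be compared like for like.

**Hodge block dynamics.** The signed incidence matrix `B_m` maps
m-simplices to their (m−1)-faces; with simplices stored as strictly
increasing vertex tuples, deleting the vertex at (0-based) position `p`
contributes the sign `(−1)^p`, so an edge `[i, j]` carries `−1` at `i` and
`+1` at `j`. The m-th Hodge Laplacian is `L_m = B_mᵀB_m + B_{m+1}B_{m+1}ᵀ`
(empty matrices at the ends), `L_0` is the graph Laplacian `K − A`, and the
total operator `L` is block-diagonal over dimensions. The flow `ẋ = −Lx`
assigns one scalar per simplex. Its structure dictates its pathologies, all
of which the package surfaces as diagnostics rather than hiding:

* the kernel dimension of `L_m` is the Betti number `β_m`; any block with
  `β_m = 0` decays to zero whatever the initial state;
* mass `Σx` is not conserved, and there is no global consensus: each
  dimension settles independently;
* because `L_m` is not an M-matrix in general, nonnegative states can turn
  negative once simplices of the same dimension interact through shared
  cofaces (see below for when this is visible).

**Metaplex dynamics.** Alternatively, each simplex *is* a continuous
domain: a point, a unit segment, or a unit equilateral triangle. Domains
exchange density only across dimension-adjacent incidences — a triangle
with each of its three edges, an edge with its two endpoints — through
sink–source regions on the matching boundaries. Discretized (next section),
the dynamics are

```
D ∘ u̇ = −S u,      S = blockdiag(stiffness) + C,
```

with `D` the concatenated lumped masses and `C` adding, per matched node
pair `(a, b)` of conductance `κ`, `+κ` to both diagonals and `−κ` to both
off-diagonal entries. `S` is symmetric with zero column sums: total mass
`Σ D∘u` is conserved exactly, `−S` is Metzler so nonnegativity is
preserved, and on a connected complex the unique steady state is the
uniform density `Σ D∘u₀ / Σ measure` — a genuine global consensus.

## Discretization choices

The continuous Laplacian on each domain is discretized by piecewise-linear
(P1) finite elements with a lumped (diagonal) mass matrix.

* **Segments** are paths of `n` nodes with the tridiagonal P1 stiffness
  (`1/h` scale, zero row sums) and lumped masses `h/2, h, …, h, h/2`
  summing to the unit length.
* **Triangles** use a uniform structured triangulation of the unit
  equilateral triangle with `n` nodes per side, `n(n+1)/2` nodes in total;
  `n = 20` gives the 210-node reference mesh. Every element is equilateral,
  so the assembled stiffness has off-diagonals `−1/(2√3)` per element edge
  (doubled on interior edges) — non-positive throughout, which is exactly
  the M-matrix property that makes the coupled flow positivity-preserving.
  A structured mesh was chosen over an unstructured mesher for determinism:
  the same call always yields the same matrices, which the tests rely on.
* **Mass normalization.** The triangle's geometric area is √3/4; its lumped
  mass is rescaled to sum to 1 so that *every* simplex has unit measure.
  The consensus density is inversely proportional to each domain's measure,
  so without this step triangles would equilibrate at a different
  cumulative density than edges or vertices.
* **Boundary matching.** Faces are listed corner-to-corner in increasing
  vertex order. Because simplices are stored as increasing tuples, the k-th
  boundary node of a triangle side pairs with the k-th node of the edge
  domain with no further orientation bookkeeping, and shared corners of
  adjacent sides coincide (they belong to both sides' matchings; the
  alternative of excluding corners from one side is representable by
  passing explicit pair lists to the constructor but is not the default).
* **Conductance.** Each matched pair defaults to conductance `κ = 1`
  (`kappa_mode = "per_pair"`), so matched pairs behave as unit-weight graph
  edges between the meshes. This makes the domain-level exchange rate grow
  with resolution — a triangle side with 20 matched pairs passes 20 units
  of conductance. The `"normalized"` mode divides `κ` across the pairs of
  a sink–source, making the domain-level rate resolution-independent. No
  canonical value exists for this constant; it is a model parameter with
  units mass·time⁻¹ per unit density difference, kept explicit.
* **Resolution.** One shared `nodes_per_edge` controls every domain. The
  reference description of the meshes is internally ambiguous between 20
  and 21 nodes per side; the package exposes the single parameter and takes
  no position, with `n = 20` as the default that reproduces the 210-node
  triangle count. Tetrahedral domains are not meshed: a complex may hold
  3-simplices, but `build_metaplex()` refuses them.

## Integration

`integrate_metaplex()` advances `D∘u̇ = −Su` by implicit Euler:
`(D + dt·S) u⁺ = D∘u`, with one sparse Cholesky factorization reused across
all steps. Two structural facts make this scheme exact where it matters:
`1ᵀS = 0` gives `1ᵀDu⁺ = 1ᵀDu` — mass conservation to round-off at any
`dt` — and `D + dt·S` is an M-matrix, so its inverse is nonnegative and
nonnegative states stay nonnegative unconditionally. Crank–Nicolson is
available for accuracy cross-checks (the suite verifies the two schemes
converge to each other at first order in `dt`); it trades the
unconditional positivity guarantee for second-order accuracy. Defaults are
`dt = 0.01` and `10⁴` steps; absolute time units are arbitrary, so
convergence-sensitive assertions use relative-change criteria
(`steady_tol`) rather than a fixed horizon. Dense eigendecomposition drives
the Hodge model (`spectral_solution()`), which is exact on the grid; the
systems of interest stay well below the size where sparse ODE integration
would be needed.

Degenerate inputs: a disconnected complex has one consensus per component
(the kernel of `S` is spanned by component indicators; the steady-state
oracle in the tests projects onto the full kernel, so it covers this case),
and an isolated domain relaxes to its own mass spread uniformly.

## Observables and diagnostics

* `per_simplex_totals()` sums `D∘u` within each domain — one number per
  simplex per time, directly comparable with the Hodge block state.
* `consensus_value()` is `Σ D∘u₀ / Σ measure`; with unit measures, total
  mass over the number of simplices.
* `return_probability()` for a delta initial condition: the metaplex limit
  is the strictly positive consensus share (1/13 on the five-vertex
  reference complex), while Hodge blocks with `β_m = 0` decay to zero.
* `detect_holes()` flags triangles whose mass at a pre-consensus snapshot
  stays below `θ` times the consensus value, reporting alongside the
  interior/boundary density ratio. Defaults: `θ = 0.1`, snapshot at the
  first saved time where the relative change per step drops below `1e-4`.
  "Almost empty" has no canonical definition; `θ` is a knob, and the
  snapshot matters — interior depletion is a transient of the influx phase
  (mass enters triangles through their sides), so on dense, coarsely
  meshed complexes it fades quickly, and it persists longer at higher
  resolution.
* `compare_models()` runs both models from one per-simplex mass table on a
  shared grid and tabulates minimum value, mass drift, distance from
  consensus and convergence time per model.

## The reference fixtures and what they can show

`fig4_complex()` — five vertices, edges {12, 13, 23, 34, 35, 45},
triangles {123, 345} — is the package's canonical stage: 13 simplices,
Betti numbers (1, 0, 0), 545 metaplex DOFs at `n = 20`. One subtlety is
worth recording. On this complex the Hodge flow cannot produce negative
values from nonnegative initial data: the two triangles share no edge, so
`L_2` is diagonal, and within a filled triangle the gradient and curl
contributions to edge–edge coupling cancel exactly, leaving `−L_1` Metzler.
The loss of positivity that distinguishes the Hodge model therefore needs
simplices of equal dimension coupled through *partially shared* structure:
`triangle_chain_complex()` (the same graph plus edge (2,4), whose clique
closure fills triangles 123, 234, 345 in an edge-sharing chain) is the
smallest fixture in the package where the block dynamics visibly
undershoot zero (minimum ≈ −0.13 for the standard seeded initial
condition). The non-conservation, block-wise extinction and absence of
global consensus, by contrast, already appear on `fig4_complex()`.

`two_domain_metaplex()` realizes the classic observation that the
domain-level transition matrix underdetermines the dynamics: both the
adjoining-endpoints and far-endpoints variants have `T = [[−1, 1], [1, −1]]`
and the same steady state, but their transients differ for any initial
condition that is not reflection-symmetric.

## The synthetic surrogate and its limits

`random_clique_complex(n, p, seed)` (igraph's G(n, p) under a fixed seed,
then the clique complex) stands in for empirical networks; the tests use a
30-vertex surrogate at the edge density of a macaque visual-cortex
connectome (190 edges among 30 areas). What it deliberately does not
emulate: real cortical networks are far more clustered than G(n, p) at
equal density, so the surrogate has fewer triangles and different hole
structure, and its vertex labels carry no anatomy. Passing tests on the
surrogate therefore certify the machinery — conservation, positivity,
consensus, interior-vs-boundary depletion during influx — not any
empirical statement about a particular brain. Users with the real edge
list can load it with `read_edge_list()` and run the identical pipeline.

## Numerical tolerances

Rank/kernel decisions (Betti numbers, deflation, the steady-state oracle)
use a relative tolerance of `1e-8` on eigen- or singular values; exact
integer homology is out of scope. Conservation is asserted at `1e-8` over
`10⁴` steps (observed drift is ~`1e-12`), positivity at `−1e-10`, and
consensus at `1e-6` in sup-norm. Early-time negativity scans use a
geometric time grid from `1e-3` to `10`, dense enough that a sign change of
the smooth spectral solution cannot slip between grid points at the
magnitudes involved.

## Known limitations

Only dimensions ≤ 2 are meshed; couplings across a dimension gap ≥ 2,
weighted or directed complexes, normalized Hodge Laplacians, and
reaction–diffusion or synchronization dynamics are out of scope. The
per-pair conductance convention ties the inter-domain rate to mesh
resolution unless `"normalized"` is chosen. Serialization is plain text
(JSON complexes, CSV trajectories and tables, MatrixMarket operators).
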