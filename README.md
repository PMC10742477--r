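# metaplexr

Diffusion on simplicial complexes modeled as **metaplexes**: networks whose
"nodes" are continuous domains — the simplices themselves — exchanging mass
through sink–source regions on their shared boundaries.

## The problem

Many complex systems carry interactions beyond pairwise links. A standard
higher-order representation is the simplicial complex: vertices, edges,
filled triangles, and so on, closed under taking faces. The usual way to put
diffusion on such a complex is through its **Hodge Laplacians**. With signed
incidence matrices `B_m` (entries are the permutation signs that order each
face into its coface),

    L_m = B_mᵀ B_m + B_{m+1} B_{m+1}ᵀ ,       L = blockdiag(L_0, …, L_M),

`L_0 = K − A` is the ordinary graph Laplacian and the kernel dimension of
`L_m` is the Betti number `β_m`. Running `ẋ = −L x` looks like diffusion but
is not: blocks with `β_m = 0` decay to zero regardless of the initial
condition, nonnegative states can turn negative, total mass is not
conserved, and vertices, edges and triangles settle at unrelated steady
states — there is no global consensus.

The alternative implemented here treats each simplex as what it
geometrically is: a point, a unit segment, or a unit equilateral triangle,
discretized by piecewise-linear finite elements with lumped mass normalized
so every simplex has measure 1. Each triangle side is matched node-for-node
to the domain of the corresponding edge, and each segment endpoint to its
vertex, with a conductance per matched pair. The semi-discrete dynamics

    D ∘ u̇ = −S u ,   S = blockdiag(stiffness) + coupling Laplacian

are symmetric with zero column sums, so the flow conserves total mass, keeps
nonnegative data nonnegative (−S is Metzler), and converges on a connected
complex to the global consensus density `Σ D u₀ / Σ measure`. The package
builds both models from the same complex, integrates them, and compares
them: per-simplex trajectories, return probabilities, and detection of
"almost empty" triangles that behave like topological holes.

## Worked example

```r
library(metaplexr)

K <- fig4_complex()          # 5 vertices, 6 edges, 2 filled triangles
glance(K)
#>   max_dim n_simplices n_vertices n_edges n_triangles euler_characteristic
#> 1       2          13          5       6           2                    1

M <- build_metaplex(K, nodes_per_edge = 20)
M
#> <metaplex> 13 domains (5 of dim 0, 6 of dim 1, 2 of dim 2), 545 DOFs,
#>            18 sink-sources, kappa = 1 (per_pair)

ic <- data.frame(simplex = c("0:1", "1:1-2", "2:1-2-3"), mass = 1)
traj <- integrate_metaplex(M, initial_condition(M, ic),
                           diffusion_config(dt = 0.01, n_steps = 10000))
glance(traj)
#>   n_dof n_simplices total_mass mass_drift min_state consensus
#> 1   545          13       3.00   1.26e-12         0     0.231
```

Three units of mass stay three units (`mass_drift ≈ 1e-12`), the state never
goes negative, and every one of the 13 simplices ends at the consensus mass
3/13 ≈ 0.231. The same initial condition under the block Hodge Laplacian
behaves very differently:

```r
compare_models(K, M, ic, diffusion_config(dt = 0.05, n_steps = 2000))$summary
#>   model    min_value mass_drift consensus_distance convergence_time conservative
#> 1 hodge    -5.55e-17   2.00e+00           2.31e-01              5.6 FALSE
#> 2 metaplex  0          1.99e-11           4.60e-10             28.1 TRUE
```

The Hodge run loses two of its three mass units (the edge and triangle
blocks have `β_m = 0` and die out) and stops far from consensus; the
metaplex run conserves mass and converges — more slowly, because it also
resolves diffusion inside each simplex. A delta of mass on triangle
(1,2,3) returns a stabilizing, strictly positive share of its mass:

```r
rp <- return_probability(integrate_metaplex(M, ic_delta("2:1-2-3"),
                           diffusion_config(dt = 0.01, n_steps = 10000)),
                         "2:1-2-3")
tail(rp, 1)$p   # 0.0769 = 1/13
```

A thin command-line front end over the same functions ships in
`inst/scripts/smx` (`smx build-complex`, `smx diffuse`, `smx detect-holes`,
`smx compare`, `smx fixture`).

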