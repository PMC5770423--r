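# cliquenet

Binary Hopfield networks whose noise-tolerant memories are **all the
k-cliques** of a graph — an attractor count that grows exponentially in the
square root of the neural population, against the classical ~n/(4 ln n)
capacity of outer-product learning. The package is aimed at computational
neuroscientists and researchers in associative memory / error-correcting
codes who want an exact, testable implementation of the construction:
threshold dynamics, minimum-probability-flow learning, the symmetric
three-parameter design with closed-form optima, stability certificates with
an exhaustive-enumeration oracle, and the combinatorial limits of
permutation-storing networks.

## The model

Neurons are the n = v(v−1)/2 potential edges of a graph on v vertices, so a
network state *is* a graph. A state `x ∈ {0,1}^n` has energy

    E_x = −½ xᵀWx + θᵀx,

with W symmetric and zero-diagonal. Asynchronous updates set
`x_e = 1  iff  ⟨W_e, x⟩ > θ_e` (ties → 0); each update lowers the energy by
`Δx_e(I_e − θ_e)`, so dynamics always halts in a fixed point. Storage is
designed in the permutation-symmetric family: weight `x` between edges
sharing one vertex, `y` between disjoint edges, uniform threshold `z`.
Storing all k-cliques r-stably is equivalent to four strict linear
inequalities `M·(x,y)ᵀ < (−2,−2,2,2)ᵀ z`, and two closed forms matter:

- flow-optimal weight `x = 2z/(3k−5)` (`mpf_optimal_x`), the unique
  minimizer of the probability flow over all k-cliques on v = 2k−2;
- large-deviation robust weight `x = z(3+2p)/(4k(1+2p))`
  (`large_deviation_x`), the midpoint of the concentration window for
  design corruption p.

Weights can also be *learned*: the probability flow
`(1/|X|) Σ_x Σ_e exp((E_x − E_{x·flip e})/2)` is convex, avoids the
partition function, and is driven toward zero exactly when the training
patterns become strong attractors (`fit_mpf`, L-BFGS-B; `mpf_learning_step`
for the local synaptic rule).

## Worked example

```r
library(cliquenet)

params <- params_flow_optimal(8, v = 16)   # x = 2/19, y = 0, z = 1
net    <- build_network(params)
net
#> Hopfield network: 120 neurons (7260 free parameters)
#>   weight range [0, 0.1053], threshold range [1, 1]

## the design is certified 1-stable: every pattern within one bit flip
## of any 8-clique returns to it in one sweep
stability_certificate(8, 1, params)
#> r-stability certificate (k = 8, r = 1): SATISFIED
#>   slacks: 0.3158, 0.5263, 0.3158, 0.5263

cl <- clique_state(c(2, 3, 5, 8, 9, 11, 14, 16), 16)
damaged <- cl
damaged[edge_index(2, 3, 16)] <- 0L   # delete a clique edge
damaged[edge_index(1, 2, 16)] <- 1L   # add a spurious edge
res <- converge(damaged, net)
res
#> dynamics_result: converged in 2 sweep(s), final energy 10.3158
identical(res$fixed_point, cl)
#> [1] TRUE
```

The recovered fixed point is the clique itself (energy
`−x·S1 + z·#E = −28·12/19 + 28 = 10.32` — the certificate's promise made
concrete). Learning instead of designing:

```r
fit <- fit_mpf(random_cliques(16, 8, 400, seed = 2))
fit
#> MPF fit: flow 120 -> 5.21976e-05 in 26 evaluations (converged)
mean(is_fixed_point(random_cliques(16, 8, 200, seed = 3), fit$network))
#> [1] 1
```

400 training cliques — about 3% of the 12,870 total — already store *every*
held-out 8-clique. A whole range of clique sizes fits in one network as
long as the size ratio stays below D ≈ 13.93:

```r
range_bounds(5, 15)
#> clique range [5, 15]: storable (x_M = -0.23429 < x_m = -0.087532)
round(mpf_optimal_x(64), 4); round(large_deviation_x(64, 0.25), 4)
#> [1] 0.0107
#> [1] 0.0091
```

A command-line front end mirrors the main entry points
(`exec/cliquenet mpf-optx --k 64`, `certify`, `robustness`,
`hidden-clique`, ...); see `?cliquenet_cli`.

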