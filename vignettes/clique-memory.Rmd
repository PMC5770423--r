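---
title: "Exponential clique memory in binary Hopfield networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exponential clique memory in binary Hopfield networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliquenet)
```

## The model

A Hopfield network couples $n$ McCulloch–Pitts binary neurons through a
symmetric, zero-diagonal weight matrix $W$ and thresholds $\theta$. A state
$x \in \{0,1\}^n$ has energy

$$E_x = -\tfrac12 x^\top W x + \theta^\top x,$$

and the asynchronous dynamics visits neurons in some order, setting
$x_e = 1$ exactly when the feedforward input $I_e = \langle W_e, x\rangle$
strictly exceeds $\theta_e$ (ties give 0). Each update changes the energy by
$-\Delta x_e (I_e - \theta_e) \le 0$, so the dynamics always terminates in a
fixed point — a *memory*. `cliquenet` studies networks whose memories are
the $k$-cliques of a graph on $v$ vertices: neurons are the
$n = \binom{v}{2}$ potential edges, so a state *is* a graph, and the number
of stored patterns $\binom{v}{k}$ grows exponentially in $\sqrt{n}$.

Three layers are provided:

1. **Dynamics** (`converge()`, `run_sweep()`, `p_corrupt()`): exact
   asynchronous threshold dynamics, dense or — for the symmetric family —
   via an $O(n)$-per-sweep degree-bookkeeping path. The two paths are
   asserted bit-identical at $v \le 16$.
2. **Learning** (`probability_flow()`, `fit_mpf()`,
   `mpf_learning_step()`): minimum probability flow (MPF), the convex
   objective $\frac{1}{|X|}\sum_{x\in X}\sum_{e}
   \exp\!\big((E_x - E_{x^e})/2\big)$ over single-bit-flip neighbors
   $x^e$. It avoids the partition function, is near zero iff the training
   patterns are strong attractors, and its gradient yields a local,
   Hebbian-flavored synaptic rule.
3. **Design** (`symmetric_params()` and friends): the permutation-symmetric
   three-parameter family — weight $x$ between edges sharing one vertex,
   $y$ between disjoint edges, uniform threshold $z$ — in which clique
   storage reduces to four linear inequalities, with closed-form optimal
   and robust settings.

## Parameters that matter

| Parameter | Meaning | Default / formula | Why |
|---|---|---|---|
| $x$ | shared-vertex weight | `mpf_optimal_x(k, z)` $= 2z/(3k-5)$ | unique flow minimizer over all $k$-cliques on $v = 2k-2$ at fixed $z$ |
| $x$ (robust) | large-deviation setting | `large_deviation_x(k, p, z)` $= z(3+2p)/(4k(1+2p))$ | midpoint of the window $(z/2k,\; z/(k(1+2p)))$ pinned by corrupted-degree concentration |
| $y$ | disjoint-edge weight | 0 | sparse connectivity; the analytic settings live in the $y = 0$ slice |
| $z$ | threshold | 1 | pure gauge: dynamics and certificates are invariant under $(x,y,z)\mapsto(cx,cy,cz)$, $c>0$ |
| $r$ | stability radius | — | `stability_certificate(k, r, params)`: all $k$-cliques attract everything within Hamming distance $r$, in one sweep |
| `order_policy` | neuron visiting order | ascending (`converge()`), random-per-sweep (experiments) | the source material does not state the order used; both are provided and experiments record theirs |

Tie-breaking is the strict rule ($I_e = \theta_e \Rightarrow 0$).
Convergence is declared after one full idle sweep, and the reported sweep
count includes that idle pass. `max_sweeps` defaults to $n$ and exhausting
it is treated as an invariant violation, not a result.

## Certificates, enumeration, and which printed formula survives

`stability_certificate()` evaluates the four strict inequalities
$M(x,y)^\top < (-2,-2,2,2)^\top z$ built from the two extreme
$r$-perturbations (strip $r$ edges at one clique vertex; attach $r$
spurious edges to one outside vertex). With $y = 0$ this gives the
feasibility window $z/(2(k-2)-r) < x < z/(k-1+r)$, nonempty iff
$2r < k - 3$.

A companion derivation in the source material displays
$z/(2(k-1)-r) < x < z/(k-1+r)$ (nonempty iff $k > 2r+1$) and claims
$\lfloor k/2 \rfloor$-stability is attainable. The two disagree, so the
package treats **exhaustive enumeration as ground truth**
(`exhaustive_r_stability()`: every clique, every state within distance
$r$, refusal rather than silent sampling past its cap). Enumeration sides
with the matrix form everywhere tested: points inside the displayed
interval but below the matrix lower bound are *not* $r$-stable, and at
$k = 6,\ r = 2$ (matrix window empty, displayed window not) no $x$ works
at all. `feasible_x_interval()` returns both windows, labeled, so the
discrepancy stays visible.

## What the synthetic generator emulates — and what a green test establishes

All experiments are synthetic by design: training sets are uniformly
random $k$-subsets encoded as clique states (`random_cliques()`), and
noise is an exact binary symmetric channel (`p_corrupt()`), the noise
model under which the robustness theory is stated. No real data enters;
what the generator does *not* emulate is any structured or adversarial
noise, degree-correlated corruption, or graphs whose planted structure is
not a clique.

The asymptotic theory promises recovery with high probability as
$k \to \infty$ — up to $p < 1/4$ for the flow-optimal setting and
$p \to 1/2$ for the large-deviation family. At desk scale those
$o(\sqrt{k}\ln k)$ corrections are not small: the binding quantity is the
*minimum* corrupted vertex degree, and at $k = 32$–$64$ it dips below the
firing threshold already near the design corruption level. Concretely,
at $k = 64, v = 128$ exact recovery under the large-deviation setting is
$\approx 1$ for $p \le 0.1$ but only $\sim 0.3$ at $p = 0.25$, with
failures losing a vertex or recruiting one (or collapsing to the complete
graph once outside vertices are recruited en masse). The acceptance
criteria that transcribe the asymptotic claims to $k = 32$ therefore fail
honestly in this package, and the passing tests establish the finite-size
facts instead: certified-radius recovery is exact, degradation in $p$ is
monotone under common random numbers, and the dense and sparse dynamics
agree bit for bit.

The same honesty applies to the permutation (Hopfield–Platt) analysis:
the $k(k-2)$ critical pairs of a derangement do **not** have disjoint
critical edges (pairs sharing a source letter share its outgoing edge),
so the product form $1-(1-4(1-p)^2p^2)^{k(k-2)}$ overstates the
Monte-Carlo union frequency; the per-pair marginal $4(1-p)^2p^2$ is
validated exactly by $2^4$ enumeration. Pairs with
$j = \sigma(\sigma(i))$ are rejected as degenerate (the fourth flip would
need a diagonal slot); perfect matchings (even $k$) have none and attain
the nominal count.

## Numerical choices

- **Fitting**: L-BFGS-B over the $n(n-1)/2 + n$ free parameters
  (upper-triangle of $W$ plus $\theta$; symmetry by parameterization).
  Zero initialization makes the starting objective exactly $n$ — a
  built-in self-check. Stopping: projected-gradient tolerance $10^{-6}$,
  500 iterations; the source gives no tolerances, these are package
  choices. Note that when every training pattern is storable the
  infimum (zero flow) is not attained: descent diverges along a
  max-margin ray, so fitted parameter *scales* are optimizer-dependent
  even though the stored memories are not.
- **Flow evaluation**: energy differences use the $O(n)$ identity
  $E_x - E_{x^e} = (1-2x_e)(I_e - \theta_e)$; the naive two-energy route
  exists in the test-suite as an oracle (agreement to $10^{-9}$).
- **Certificate strictness**: inequalities are strict; slacks below
  $10^{-12}$ are flagged `marginal` rather than decided.
- **1-D cross-checks**: the closed-form minimizer is verified against a
  bracketed root of the central-difference derivative (accuracy
  $\sim 10^{-12}$); golden-section search cannot reach the $10^{-8}$
  comparison tolerance.
- **Seeding**: every stochastic entry point takes a `seed` and restores
  the caller's RNG state; experiment tables embed their full
  configuration as metadata.

## A worked storage run

```{r}
params <- params_flow_optimal(8, v = 16)     # x = 2/19, y = 0, z = 1
net <- build_network(params)
cl <- clique_state(c(1, 3, 5, 7, 9, 11, 13, 15), 16)
damaged <- cl
damaged[edge_index(1, 3, 16)] <- 0L          # certified radius r = 1
res <- converge(damaged, net)
identical(res$fixed_point, cl)
res$sweeps
```

```{r}
fit <- fit_mpf(random_cliques(16, 8, 400, seed = 2))
mean(is_fixed_point(random_cliques(16, 8, 200, seed = 3), fit$network))
```

## Known limitations

- Fixed points other than cliques exist (stars, the complete graph); the
  package reports them (`hidden_clique_solve()`) but, like the theory, has
  no complete characterization.
- Finite-temperature (Glauber) dynamics, partition functions, and
  likelihood/contrastive-divergence estimation are out of scope.
- The permutation module builds the combinatorial impossibility machinery
  only; no permutation-storing network is constructed.
- Full published scales ($v = 80$ training, $v = 128$ robustness) run in
  seconds-to-minutes here but are exercised at reduced trial counts in the
  test-suite to stay inside its time budget.
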