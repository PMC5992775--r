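---
title: "Exact population simulation of Boolean networks in the product basis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact population simulation of Boolean networks in the product basis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolpop)
```

## The problem

A Boolean network describes a cell (or any discrete system) by $N$ ON/OFF
variables $B_1,\dots,B_N$, each updated synchronously by a logic rule of a
few inputs. A *population* of such cells is a weighted mixture of the $2^N$
possible states. When the mixture is very heterogeneous — say, a uniform
mixture over $10^{10}$ activation states, or every combination of
loss-of-function mutations at a small per-gene rate — neither enumerating
subpopulations nor Monte Carlo sampling is workable: enumeration scales with
the number of subpopulations, and sampling cannot resolve subpopulations
present at $10^{-12}$ of the population.

`boolpop` simulates such populations *exactly*. The output is, for each
tracked quantity, the population fraction over time — including co-occurrence
fractions like $\langle A \wedge B\rangle$ that carry the correlation
information lost by marginal averages.

## The product basis

For a subset $\alpha$ of the model variables define the product variable

$$x_\alpha = \prod_{i \in \alpha} B_i \in \{0, 1\}, \qquad x_\emptyset = 1 .$$

For an individual in state $\kappa$ (the set of ON variables),
$x_\alpha = [\alpha \subseteq \kappa]$. The vector $\mathbf{x}$ over all
$2^N$ subsets is related to the state-indicator vector $\mathbf{b}$
(one entry per full state) by the zeta matrix of the subset lattice,
$\mathbf{x} = T\mathbf{b}$ with $T_{\alpha\kappa} = [\alpha \subseteq
\kappa]$; its inverse is the Möbius matrix with entries
$(-1)^{|\kappa|-|\alpha|}[\alpha \subseteq \kappa]$
(`change_of_basis()`, `invert_change_of_basis()`). Both are exact integer
matrices; the package validates $T T^{-1} = I$ directly.

The point of the basis change is that population-level questions are
naturally linear in $\mathbf{x}$: the population average
$\langle x_\alpha\rangle$ is the fraction of individuals with all of
$\alpha$ ON, and a closed linear system in a *few* product variables can
evolve a mixture of arbitrarily many subpopulations.

## Building the linear system

Three operations produce the system:

1. **Single rules** (`single_rule()`). A variable $i$ with inputs
   $\theta^{[i]}$ and truth table $k^{[i]}$ updates as
   $f_i = k^{[i]}(T^{(N^{[i]})})^{-1}\mathbf{x}^{[i]}$ — a linear
   expression over subsets of its inputs. The coefficient of $x_\kappa$ is
   the subset Möbius transform
   $\sum_{\alpha \subseteq \kappa}(-1)^{|\kappa|-|\alpha|}k_\alpha$,
   computed with the fast $O(n2^n)$ in-place transform, so the $2^n$
   matrix is never materialised.
2. **Products** (`reduce_product()`). A multi-index variable updates as
   the product of its members' rules,
   $f_{ij\ldots} = f_i f_j \cdots$; after distributing, every monomial
   $x_\beta x_\gamma$ collapses to $x_{\beta\cup\gamma}$ because Boolean
   indicators are idempotent ($x^p = x$). Factors are folded in one at a
   time with like-term merging after each multiplication, which keeps
   intermediate expressions small.
3. **Closure** (`close_system()`). Starting from the tracked subsets
   $\Omega_0$, solve each pending rule and enqueue every subset that
   appears on a right-hand side until every referenced subset has a rule.
   The worklist is FIFO and term order canonical (ascending subset mask),
   so the ordering of the tracked set — and hence the operator layout — is
   reproducible run to run. Termination is guaranteed (there are finitely
   many subsets) and asserted on exit.

`assemble_operator()` stores the result as a sparse matrix $F$ with
$\mathbf{x}(t+1) = F\,\mathbf{x}(t)$. Because $F$ is linear it evolves any
mixture: evolution commutes with the population average (superposition),
which the test suite checks exactly on random mixtures.

A useful internal cross-check, used throughout the tests: a multi-index
rule can also be derived by building the AND of the member truth tables
over the union of their input sets and Möbius-transforming that table. The
two routes agree term-for-term on random networks.

## Populations

`initial_moments()` builds $\langle x_\alpha\rangle(0)$ for each tracked
subset from a population specification:

* `pop_uniform()` — uniform mixture of activation states,
  $\langle x_\alpha\rangle = 2^{-|\alpha|}$;
* `pop_marginals(p)` — independent per-variable ON probabilities;
* `pop_states(states, weights)` — explicit weighted state list (weights
  must sum to 1; the package fixes the normalization $W = 1$ throughout,
  so moments are fractions);
* `pop_knockout(mu, p)` — for a wild-type-augmented network: each gene's
  `.WT` variable is independently lost with probability `mu`, activation
  is uniform (or `p`), and mutated genes always begin OFF. Moments are
  computed as a product of per-gene factors
  ($P(\mathrm{gene}) = p_i(1-\mu)$, $P(\mathrm{WT}) = 1-\mu$, gene ON
  $\Rightarrow$ WT intact) — never by enumerating mutational profiles,
  which is what makes populations spanning $\sim 2^{2N}$ subpopulations
  tractable.

`augment_wildtype()` performs the loss-of-function augmentation: a constant
variable `A.WT` is ANDed into A's rule, so `A.WT = 0` encodes a permanent
knockout. With all `.WT` variables ON the augmented network's trajectories
are identical to the original's (tested by direct simulation).

## Probabilistic and continuous time

For probabilistic networks (PBNs) the truth table generalises to a vector
of ON-likelihoods, and the same machinery applies; the resulting system is
exact for the *infinite-population* average (the per-individual process is
stochastic and does not close). `attach_rates()` builds the standard
rate-augmented PBN $f'_i = (1-r_i)x_i + r_i f_i$: $r_i = 1$ is the
deterministic update, $r_i = 0$ freezes the variable. Asynchronous
networks are handled by this same mapping with $r_i = \mathrm{rate}_i\,
\Delta t$ for a small user-chosen $\Delta t$; the approximation is good
when per-step update probabilities are small (the Monte Carlo reference
uses a 0.05 ceiling as its own rule of thumb).

In continuous time the rule of a multi-index variable follows the product
rule of derivatives, $f_{AB\cdots} = x_Bx_C\cdots f_A + x_Ax_C\cdots f_B +
\cdots$ (`differential_rule()`), and $f_\emptyset = 0$ so the total weight
is conserved. The source formalism defines $f_i = dx_i/dt$ but leaves open
how the single-variable rate derives from the logic rule; this package
defines

$$f_i = r_i\,(g_i - x_i),$$

relaxation at rate $r_i$ (default 1) toward the discrete logic target
$g_i$. This is the unique continuous limit of the discrete rate
augmentation above, and at the individual level it corresponds to a Markov
jump process in which variable $i$ flips toward its target at rate $r_i$ —
which is exactly the master equation the reference oracle integrates, so
the interpretation is checked, not just asserted.

## Reference simulators

Because the engine's claim is exactness, the package ships deliberately
brute-force oracles to check it against:

* `simulate_individual()` — direct synchronous rule application;
* `simulate_pbn_population()` — Monte Carlo over sampled individuals, with
  standard errors (per-variable updates are independent given the state);
  one master seed drives reproducible per-run streams;
* `state_space_oracle()` — exact evolution of the full $2^N$ distribution
  (deterministic map, stochastic master-equation matrix, or continuous
  master equation), refused above $N = 12$ on purpose.

The validation protocol (`pb_validate()`) mirrors the method's published
evaluation at sizes chosen to keep a desk run in minutes: 200 random
10-node deterministic networks (in-degree 1–4, i.e. $\sim$25 edges,
uniform initial mixture, 30 steps) checked for *exact* equality with the
oracle; 100 rate-augmented PBNs checked against the exact master equation
($\le 10^{-9}$) and against $10^4$-run Monte Carlo (within $4/\sqrt{n}$);
25 random 6-node continuous networks checked against the state-space ODE
oracle at $10^{-6}$. Exactness in the deterministic case is not a
tolerance choice: uniform-mixture moments are dyadic rationals with
denominator $2^N$ and the operator is integer, so double arithmetic is
exact throughout.

What the random-network generator does *not* emulate: real signalling
topologies (it draws inputs uniformly, allows self-inputs by default, and
permits truth tables that ignore an input — both behaviours are flags
recorded in the network's provenance attribute), canalising rule biases,
and scale-free degree structure. Passing these ensembles therefore
demonstrates the algebra is right, not that any particular biological
model is.

## Numerical choices and caps

* Coefficients are exact integers for deterministic networks (drop
  tolerance 0 — cancellations land exactly on zero); probabilistic and
  continuous systems use floating point with a $10^{-12}$ drop tolerance
  so that cancelled terms do not linger as noise.
* Subsets are bit masks stored in doubles (exact to $2^{52}$), which caps
  networks at 52 variables; wild-type augmentation doubles the variable
  count, so models above 26 variables cannot be fully augmented. Larger
  models need a wide-mask representation that this version does not
  implement.
* Per-rule input cap 20 and closure cap $10^6$ tracked subsets, both
  configurable; closure can be exponential in bad topologies (downstream
  feedback especially), so exceeding the cap fails loudly with the
  frontier subsets named.
* Continuous integration uses the adaptive Dormand–Prince method
  (`deSolve::ode`, `ode45`) with relative tolerance $10^{-8}$ by default
  (the oracle runs at $10^{-10}$); these defaults are this package's own,
  stated rather than inherited.
* Degenerate inputs: a parsed rule's input set is exactly the variables
  appearing in its expression; explicit `table:` rules may declare inputs
  their table ignores, and serialization in `table` format preserves them
  (the `expr` format drops the input list only for constant rules).

## Limitations

* Individuals are non-interacting; there is no cell division, death, or
  population-size dynamics.
* Only loss-of-function (AND-gated wild-type) augmentation is provided;
  gain-of-function and per-edge perturbations are not.
* Closure size is model-dependent and can explode; the caps make that an
  error, not a hang.
* Attractor-oriented equation reduction is out of scope — the engine
  reports exact transients and steady levels of the tracked quantities,
  not a catalogue of attractors.
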