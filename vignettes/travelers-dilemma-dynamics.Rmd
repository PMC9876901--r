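---
title: "Dynamics of the Traveler's Dilemma: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics of the Traveler's Dilemma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The game and its two levels

In the Traveler's Dilemma two players each claim an integer $n_i$ in
$[L, U]$. Equal claims are paid as claimed; when claims differ, the lower
claimant receives their claim plus a reward $R > 1$ and the higher claimant
receives the lower claim minus $R$:

$$\pi_{ij} = \begin{cases} n_i & n_i = n_j \\ n_i + R & n_i < n_j \\
n_j - R & n_i > n_j. \end{cases}$$

Undercutting by one always pays, so iterated elimination of dominated
strategies drives both players to the unique Nash equilibrium $\{L, L\}$
(the "stairway to hell"), even though both would earn far more by jointly
claiming high values.

The package's starting point is that this tension is structural: restricted
to a close pair of claims $\{n, n+s\}$ with $1 \le s \le R - 1$, the game is
a Prisoner's Dilemma (the lower claim strictly dominates, mutual play of the
higher claim Pareto-dominates) — the *local* game. Restricted to a distant
pair with $s \ge R$ it is a coordination game whose payoff-dominant
equilibrium is the high claim — the *global* game. `classify_pair()`
implements this decomposition exactly; risk dominance between the two
equilibria of a coordination pair follows the Harsanyi–Selten criterion,
which for this game reduces to the high claim being risk dominant iff
$s > 2R$. For non-integer $R$ the two ranges leave a gap
($R - 1 < s < R$); such pairs are classified by direct best-response
analysis of the 2×2 restriction rather than by extrapolating either
inequality.

Escaping the Nash equilibrium requires the optimisation to jump from the
local to the global level, and all three dynamics below show that the jump
happens exactly when *diversity* — the sustained presence of strategies far
apart in the claim space — is maintained.

## Replicator–mutator dynamics

For an infinite population with claim frequencies $x_i$,

$$\dot x_i = \sum_j x_j f_j(\vec x)\, q_{ji} - x_i \phi, \qquad
f_i = \sum_j \pi_{ij} x_j, \qquad \phi = \sum_i x_i f_i,$$

with the uniform mutation kernel $q_{ij} = q/(n-1)$ for $i \ne j$,
$q_{ii} = 1 - q$, $0 \le q \le (n-1)/n$. At $q = 0$ this is the replicator
equation; at $q = (n-1)/n$ mutation is completely symmetric.

Numerical choices:

* **Initial condition.** All equilibria reported by the package start from
  the uniform state $x_i = 1/n$, the symmetric choice in the absence of any
  privileged prior. The published equilibrium claims for the full space
  (highest-frequency claim 96 at $q = 0.7, R = 2$; claim 2 at
  $q = 0.2, R = 30$) are reproduced from this start, so basin ambiguity
  never had to be resolved.
* **Integrator.** `deSolve::lsodar` with `rtol = 1e-10`, `atol = 1e-12`:
  the system is 99 coupled nonlinear equations whose trajectories hug the
  simplex boundary for long stretches, which is where loose tolerances let
  frequencies drift negative. The state is projected back onto the simplex
  (clip at 0, renormalise) only once, after integration; along the
  trajectory the drift stays below $10^{-6}$ in the sum and $10^{-9}$
  per component, which the test suite asserts.
* **Equilibrium criterion.** Integration stops at the first time
  $\max_i |\dot x_i| < 10^{-10}$ (a root function of the solver, so the
  stop is event-driven, not polled), or at `t_max = 1e5` time units with
  the run flagged unconverged. The tight derivative criterion is what makes
  the *argmax* claim stable; looser criteria can freeze the ranking before
  slow late rearrangements finish.
* **Ties.** `which.max` breaks frequency ties toward the lowest claim,
  the direction the game's own incentives point.

## Wright–Fisher dynamics

A finite population of $N$ players (default 100, the conventional size at
which drift is visible but not dominant) evolves in non-overlapping
generations: offspring are sampled with replacement with weights
$f_k = e^{\rho \Pi_k}$, where $\Pi_k$ is the claim's summed payoff against
all $N-1$ opponents (self-interaction excluded), and each offspring mutates
with probability $\mu$ by a step of at most $\delta$ claim units, clamped
to $[L, U]$.

* The exponent uses the *accumulated* payoff. Because sampling weights are
  invariant under a common shift of all $\Pi_k$, the maximum is subtracted
  before exponentiation; this makes $\rho \Pi$ values of order $10^4$ safe
  without changing the process. A `payoff_mode = "mean"` switch divides by
  $N - 1$ instead, which only rescales the effective $\rho$.
* The mutation step magnitude is drawn uniformly from $\{1, \dots,
  \delta\}$ with a symmetric sign. Reading $\delta$ as a *maximal* step
  keeps $\delta = 1$ identical to the fixed-step reading, which remains
  available as `step_dist = "fixed"`.
* The initial population draws each claim uniformly from the action space —
  the symmetric start that lets either regime (collapse to $L$ or
  stabilisation at high claims) emerge on its own.
* Runs report `c_avg_final` as the average claim over the last 100
  generations rather than the final generation alone; with $t = 1000$ the
  process has long converged in distribution and the trailing mean
  suppresses drift noise by an order of magnitude.
* All randomness flows through R's RNG; a run is a pure function of its
  parameters and `seed`, and sweeps derive per-cell child seeds
  deterministically from the master seed, so whole phase diagrams are
  replayable.

The test suite anchors the implementation to classical population-genetics
facts: under neutrality ($\rho = 0$, $\mu = 0$) claim frequencies are a
martingale and the fixation probability of $k$ copies among $N$ is $k/N$
(checked against 2000 replicated absorptions), and the sampler's step
distribution passes a chi-square uniformity check.

## Introspection dynamics

Two players hold one claim each. Per step one player, chosen with
probability 1/2, draws an alternative claim uniformly from the whole action
space and adopts it with the Fermi probability

$$p = \frac{1}{1 + e^{-\beta(\tilde\pi - \pi)}},$$

where $\pi$ and $\tilde\pi$ are the current and counterfactual payoffs
against the opponent's fixed claim. The joint claim pair is a Markov chain
on $A^2$ states (9801 for $[2, 100]$) with at most $2(A-1)$ off-diagonal
transitions per row.

* Self-proposals are included (accepted at probability 1/2 as no-ops);
  excluding them rescales every off-diagonal transition by $A/(A-1)$ and
  leaves the stationary distribution unchanged, so the inclusive convention
  is chosen for its simpler chain.
* $\beta = \infty$ is not exposed: irreducibility (and hence a unique
  stationary law) requires finite $\beta$; large finite values approximate
  strong selection arbitrarily well.

**Stationary distributions are computed exactly.** The update rule is
player-symmetric, so the chain is lumpable onto unordered claim pairs —
$A(A+1)/2 = 4950$ states for the full game. One balance equation is
replaced by the normalisation constraint and the dense lumped system is
solved by LAPACK, then unfolded symmetrically onto ordered pairs. The
residual $\lVert v^\top P - v^\top \rVert_\infty$ is evaluated on the
*full* 9801-state chain and must come in below $10^{-10}$ or the solve
errors out. This route was chosen after the obvious ones failed the
problem's structure: sparse LU on the full chain fills in catastrophically
(every claim pair couples along both coordinates), and power iteration
mixes at a rate that collapses near the phase boundary, where the chain is
metastable between the high-claim region and the Nash corner. Power
iteration remains available (`method = "power"`) and the tests require the
two routes to agree to $10^{-9}$, alongside an independent check of the
exact law against the occupancy histogram of a $10^7$-step simulated
trajectory (total variation < 0.01). The trajectory simulator itself is a
small compiled loop driven by R's RNG, so it is seed-reproducible like
everything else.

## Phase diagrams and boundary fitting

Each dynamic gets a two-parameter sweep (`rm_sweep`: $q \times R$;
`wf_sweep`: $\mu \times \delta$ with replicates; `introspection_sweep`:
$\beta \times R$). `detect_boundary()` locates, along each slice of the
first axis, the smallest second-axis value at which the cell summary first
drops into the Nash regime, interpolating linearly between the bracketing
cells; slices that never cross, or that start inside the Nash regime, carry
no information about the transition and are omitted with a message.
Replicated stochastic cells are averaged before thresholding.

Thresholds: the deterministic criterion `c_high_freq` $\le L + 1$ declares
a cell Nash when the highest-frequency claim has fallen (essentially) to
$L$; mean-claim criteria use $c_{avg} \le L + 2$, the extra unit absorbing
stochastic blur. `fit_boundary()` then fits one of four curve families by
unweighted least squares in the untransformed coordinates — $c\sqrt{q}$,
$c_0 + c_1 q$, $c/\beta$, $\alpha\mu^{-b}$ — the simplest defensible
convention when no weighting scheme is implied by the data; the
closed-form families use their exact normal equations and the power family
Gauss–Newton from a log–log start (noiseless data short-circuits to the
log–log solution, which already interpolates).

Problem sizes were chosen so that a full analysis runs on a desk machine:
the replicator–mutator sweep uses a 25×25 grid on the full action space
(each cell is an event-stopped stiff integration, well under a second);
the introspection sweep uses exact stationary solves on reward scans that
bracket the transition for each of five selection intensities
$\beta \in \{0.125, 0.25, 0.5, 0.75, 1\}$, spanning weak to strong
selection, with scan windows scaled like $1/\beta$; Wright–Fisher sweeps
default to 10 seeds per cell.

**A caution on boundary constants.** The sweep-plus-fit pipeline recovers
the replicator–mutator boundary prefactor in $R_B = c\sqrt q$ at $c
\approx 50$ robustly — the transition there is sharp, so the detected
points barely move with the threshold convention. The introspection
transition is *not* sharp at weak selection: $c_{avg}$ decays over a band
of rewards, so where the detector places the boundary depends materially
on the convention. With the foot-of-the-transition convention used here
($c_{avg} \le L + 2$) the fitted constant in $R_B = c/\beta$ comes out
near 11 (the acceptance script recomputes it); reading the borderline
mid-transition instead yields values around 9. The $1/\beta$ shape itself
is stable across conventions; the constant should be quoted together with
its detection rule.

## What the sweeps do and do not show

The sweeps are generated by the package's own dynamics under the stated
defaults (uniform initial conditions, the uniform mutation kernel, one
introspecting player per step). They characterise these models, not
behavioural data: none of the dynamics models memory, beliefs about the
opponent, asymmetric players, or populations of more than two learners in
the introspection setting, and the replicator–mutator equation has no
finite-population corrections. Passing tests demonstrate that the
implementations agree with their independent oracles (enumeration,
small-step Euler integration, neutral-drift theory, long-trajectory
histograms) and reproduce the published equilibrium claims and phase
structure; they do not validate the models against experiments with human
players.

## Known limitations

* Equilibrium detection for the ODE reports the first stall of the
  dynamics; systems with multiple attractors reachable from non-uniform
  starts are the caller's responsibility via `x0`.
* The boundary detector assumes a single monotone transition per slice; a
  re-entrant phase diagram would need a different criterion.
* The `"power"` stationary method is provided as a cross-check and is not
  practical near phase boundaries on the full action space (see above).
* Very large `steps` in `simulate_trajectory()` are memory-bound (two
  integers per step are returned).
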