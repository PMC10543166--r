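---
title: "Herding costs in evolutionary games on networks: model and methods"
author: "herdgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Herding costs in evolutionary games on networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdgame)
```

## The model

`herdgame` simulates evolutionary two-player games on structured populations
in which a *herding mentality* — the psychological discomfort of acting
differently from one's crowd — enters the game as an explicit payoff cost.

### The generalized pairwise game

Each pair of connected players plays a symmetric two-action game. With the
usual normalization that mutual cooperation pays $R = 1$ and mutual defection
$P = 0$, the game is fully described by the sucker's payoff $S$ (a cooperator
facing a defector) and the temptation $T$ (a defector facing a cooperator):

$$
\begin{array}{c|cc}
 & C & D\\\hline
C & 1 & S\\
D & T & 0
\end{array}
$$

The plane $S \in [-1, 1]$, $T \in [0, 2]$ covers the four classic regimes:
harmony ($S > 0$, $T < 1$), snowdrift ($T > 1 > S > 0$), stag hunt
($1 > T > 0 > S$) and prisoner's dilemma ($T > 1 > 0 > S$). Values outside
these ranges are accepted with a warning. Every step, player $i$ accumulates
$\Pi_i = \sum_{j \in \mathcal{N}_i} M(a_i, a_j)$ over its network neighbours;
payoffs are recomputed fresh each step, with no carry-over.

### The herding cost

A player who carries the herding mentality pays, per step, a cost
proportional to the fraction of its comparison crowd acting differently:

$$
h_i \;=\; \tau \,\frac{|C_i|}{\langle k\rangle}\, r_i ,
$$

where $C_i$ is the crowd (network neighbours, or all $Z-1$ other players in
a well-mixed population), $r_i \in [0,1]$ the fraction of the crowd whose
*action* differs from $i$'s, $\tau \ge 0$ the social weight, and
$\langle k\rangle$ the population mean degree. In local mode
$|C_i| = k_i$, so $h_i = \tau (k_i / \langle k\rangle) r_i$: hubs, who face
larger crowds, pay proportionally more for nonconformity. In the well-mixed
mode we take the reference degree to be the crowd size itself, so the
crowd-size factor cancels and $h_i = \tau r_i$. Setting $\tau = 0$ switches
the mechanism off and recovers the plain game.

Two design points here were genuinely open and deserve a note:

* **Relative-degree scaling.** The cost could equally be defined without the
  $k_i/\langle k\rangle$ factor (a pure disagreement ratio bounded by
  $\tau$). We scale by relative degree so that the cost of nonconformity
  grows with the size of the crowd a player faces, which is the reading that
  makes the crowd-size factor in the definition meaningful; for a 4-regular
  lattice the two coincide exactly, and for any degree-$\langle k\rangle$
  node they agree.
* **What counts as "different".** $r_i$ compares *actions* (C versus D)
  only, never the herding trait: the mentality is an internal disposition,
  not an observable behaviour, so a herding cooperator feels no pressure
  from a non-herding cooperator. The four-strategy game could alternatively
  compare full strategy labels; we expose the action-only rule as the single
  behaviour because that is what a crowd can actually observe.

### Update rule

After payoffs and costs are computed from the time-$t$ state, every node
updates independently (synchronously): with probability $\mu$ it redraws its
strategy uniformly from the variant's strategy set (mutation, which may
redraw the current strategy); otherwise it picks one neighbour $j$ uniformly
at random and copies $j$'s *full* strategy with the Fermi probability

$$
p \;=\; \frac{1}{1 + e^{-\beta (\Pi'_j - \Pi'_i)}},
$$

where $\beta > 0$ is the selection intensity. All replacements commit
simultaneously. Mutation and imitation are mutually exclusive within a step.

### The three game variants

Which payoffs $\Pi'$ enter the comparison defines the variant:

* `pairwise_plain` — raw payoffs; the baseline two-strategy game.
* `pairwise_herding` — $\Pi'_i = \Pi_i - h_i$ for *every* player; the
  two-strategy game with a universal herding cost.
* `four_strategy` — the asymmetric co-evolutionary game. Strategies are
  pairs (action, trait) from $\{HC, HD, \tilde H C, \tilde H D\}$, where
  $H$/$\tilde H$ is herding/non-herding. The comparison is made from the
  focal player's perspective: a herding focal discounts *both* its own and
  the model's payoff by their respective costs; a non-herding focal compares
  raw payoffs. The model's own trait never affects the pair's comparison —
  this one-sidedness is what makes the game asymmetric (a bimatrix game).
  Because imitation copies the full strategy, the herding trait itself is
  heritable and evolves.

Two-strategy variants are stored internally with the fixed non-herding trait
labels, so that the reported herder fraction of a baseline game is 0 and
herder deltas against the baseline are meaningful; in `pairwise_herding` the
cost applies to everyone regardless of the label.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $S$, $T$ | game payoffs (dimensionless, $R=1$, $P=0$ fixed) | — | the two free axes of the phase plane |
| $\tau$ | herding weight ($\ge 0$) | 1 | unit cost for a fully nonconforming degree-$\langle k\rangle$ node |
| $\beta$ | selection intensity | 5 | strong but noisy selection; mistakes remain possible |
| $\mu$ | mutation probability / step | 0.01 | sustained exploration, $\sim Z/100$ redraws per step |
| steps | synchronous steps / realization | 3000 | long enough for stationarity at these scales |
| realizations | independent Monte-Carlo runs | 30 | averages out run-to-run bistability |
| window | stationary averaging window | last 25% | discards the transient |
| lattice | torus, von Neumann neighbourhood | 70×70 | every degree exactly 4 |
| scale-free | Barabási–Albert, attachment $m$ | $m=2$ | $\langle k\rangle \approx 2m \approx 4$, matching the lattice |

The BA attachment parameter deserves a remark: a mean degree of about 4 and
$m = 3$ (which gives $\langle k\rangle \approx 6$) cannot hold
simultaneously, so the generator defaults to $m = 2$ to honour
$\langle k\rangle \approx 4$ and leaves $m$ configurable. The generator
seeds growth with a complete graph on $m+1$ nodes, which guarantees every
node a degree of at least $m$ and makes `scale_free_network(m + 1, m)` the
complete graph.

## What the simulator emulates — and what it does not

The synthetic populations are the study conditions themselves: there is no
external data. A realization initializes strategies by i.i.d. categorical
draws (25% of each strategy in the four-strategy game, 50/50 in the
two-strategy games; exact-count placement is available as a switch), runs
3000 synchronous steps, and averages the final 25% of the recorded series.
Experiments average 30 realizations by default, with a fresh scale-free
network per realization to avoid anomalous single-network artifacts.

Passing tests on these populations show that the mechanism behaves as
specified on idealized graphs; they do not show that real social networks —
which have clustering, communities, degree correlations and weighted,
time-varying ties — would behave identically.

## Numerical choices

* **Engine.** The synchronous step loop is implemented in C++ (via Rcpp) and
  consumes R's global RNG stream under a fixed draw protocol (per node: a
  mutation gate; then either a mutation pick, or a model pick plus a Fermi
  coin). A pure-R straight-line oracle in the test suite reproduces every
  payoff, cost, neighbour draw and Fermi coin and must match the engine
  bit-for-bit, so the compiled path is verified against an independent
  recomputation, and `set.seed()` makes every run exactly reproducible.
* **Seeds.** Realization $i$ of an experiment runs with seed
  `master_seed + i`; a scale-free spec is realized with that same seed. The
  whole experiment is a pure function of its configuration.
* **Overflow.** The logistic is evaluated in sign-split form, so
  $|\beta \Delta\Pi|$ in the thousands neither overflows nor produces `NaN`.
* **Degenerate inputs.** Degree-0 nodes (possible only through custom edge
  lists) are inert: payoff 0, cost 0 (with a warning from the ratio
  function), no imitation; they still mutate. Well-mixed populations are
  implicit — no $O(Z^2)$ adjacency is ever built.
* **Stationary window.** `summarize_stationary` averages the last
  `ceiling(fraction × n)` of the `n` recorded entries (a full run records
  the initial state plus one entry per step).
* **Baselines in sweeps.** A sweep cell with $\tau > 0$ is compared against
  the plain game at $\tau = 0$ with the same $(S, T)$, network specification
  and master seed; a cell with $\tau = 0$ is its own baseline, so its deltas
  are exactly zero by construction.

## Behaviour near coordination corners

In the stag-hunt region (and most extremely at $S = -1$, $T = 0$) the model
is bistable: full cooperation and full defection are both absorbing up to
mutation noise, and a realization commits to one basin within the first few
dozen steps. Stationary averages there are therefore mixtures over basin
probabilities rather than smooth coexistence values, and they carry large
Monte-Carlo standard deviations at small realization counts. The herding
cost shifts these basin probabilities toward cooperation (and, in the
four-strategy game, keeps the herding trait near one half of the population
across most of the plane), but at desk scales ($Z = 1000$, 5 realizations)
the corner outcome remains genuinely stochastic. Results quoted for such
corners should always be read together with their per-realization spread,
which `run_experiment` returns.

## Desk-scale test sizes

The test suite and the acceptance script run reduced replicas chosen as the
package's own desk-scale defaults: scale-free populations of $Z = 1000$
($m = 2$), 3000 steps, 5 realizations per cell, and a coarse
$4 \times 5$ grid over $S \in [-0.5, 1] \times T \in [0, 2]$ that excludes
the low-$S$ full-defection region when averaging herder fractions. Unit
tests use still smaller graphs (tori up to $10\times10$, scale-free graphs
of a few hundred nodes) where the property under test does not need scale.

## Known limitations

* Only Fermi pairwise imitation with synchronous commits is implemented; no
  birth–death, best-response or asynchronous schemes.
* The cost mechanism is memoryless and reactive — no reputation, emotion, or
  two-step reflexive herding.
* Payoff parameters $R$ and $P$ are fixed by normalization; payoff noise and
  weighted edges are out of scope.
* Network generators cover the torus, Barabási–Albert graphs and the
  implicit complete graph; anything else must come in as an edge list.
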