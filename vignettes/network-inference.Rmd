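---
title: "Signed signalling-network inference from perturbation time courses"
author: "perturbNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed signalling-network inference from perturbation time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbNet)
```

## The model

perturbNet reconstructs directed protein-signalling networks with two edge
types — activation (+1) and inhibition (−1) — from longitudinal
high-throughput measurements (e.g. reverse-phase protein arrays) taken after
external perturbation of some network components. The model is a dynamic
deterministic effects propagation network (DDEPN): a signed digraph
$\Phi \in \{0,1,-1\}^{N\times N}$ over the $N$ measured proteins, a designated
stimulus set, and Boolean dynamics that carry the perturbation downstream.

**Propagation.** Starting from the state in which exactly the stimuli are
active, states update synchronously: a protein is active at the next step iff
at least one activating parent is active and no inhibiting parent is active;
stimuli are clamped active throughout (an experimental input cannot be
switched off by the network). Updating stops when a previously visited global
state recurs. The distinct states visited, in order, form the columns of the
system-state matrix $\Gamma \in \{0,1\}^{N\times M}$. Propagation is
deterministic and terminates after at most $2^N$ states; in practice $M$ is
small. Each experiment (stimulation condition) gets its own $\Gamma$ from its
own stimulus set; all experiments share the emission parameters below.

**Emissions and Viterbi training.** Each measurement $d_{itr}$ (protein $i$,
time $t$, replicate $r$) is Gaussian given the protein's Boolean state:
$\mathcal{N}(\mu_i^{a},\sigma_i^{a})$ when active,
$\mathcal{N}(\mu_i^{p},\sigma_i^{p})$ when passive. Time points are linked to
$\Gamma$'s columns by a hidden assignment path constrained to be monotone
non-decreasing — the system progresses through the propagated state sequence
and may dwell or skip, but not run backwards. Parameters and path are fitted
by Viterbi training (hard EM): (a) per-protein Gaussian estimation from the
current active/passive partition (class MLE; biased variance), then (b) the
best monotone path by dynamic programming. Both steps can only increase the
attained log-likelihood (the DP is exact; the class MLE maximises given the
path, and the $\sigma$ floor can only bind in the direction that preserves
the inequality), so the training log-likelihood is monotone non-decreasing —
asserted exactly in the tests. Iteration stops when the path is stable
(typically 2–4 iterations; hard cap `maxIter = 20`).

Numerical choices: $\sigma$ is floored at $10^{-6}$; a class with no
assigned observations for some protein falls back to that protein's pooled
mean and pooled (floored) sd, which leaves the attained likelihood untouched
because no observation uses those parameters; the initial path spreads the
$T$ time points uniformly over the $M$ columns ($\lceil tM/T\rceil$); DP ties
resolve to the smallest column; optional random restarts are available via
`nStarts`.

**Scores.** With a structure prior, the (unnormalised log) posterior is
$\log P(D\mid\Phi) + \log P(\Phi)$. Without one, a BIC-penalised likelihood
is used: $\log L - \tfrac12 k \log n_{obs}$ with $k$ = number of edges plus
the $4N$ emission parameters. The penalty form is a package design decision:
the edge count must enter, or structure would be unpenalised and the score
would always prefer denser networks.

## Structure search

**inhibMCMC.** A Metropolis–Hastings sampler over signed structures with six
move types: add-activation, add-inhibition, delete, revert, switch-type and
reverse-switch. Every empty ordered pair slot admits the two additions; every
edge admits deletion and a type switch; every edge whose reverse slot is
empty admits the two reversals. Any edge state can therefore be reached from
any other in one step. Candidates are drawn uniformly over the whole
neighbourhood (not uniformly over move types), so the proposal probability is
$1/|N(\Phi)|$ and is not symmetric — an empty two-node network has 4
neighbours while the same network with one activation edge has 6 — which the
acceptance probability corrects with the Hastings factor
$|N(\Phi_k)|/|N(\Phi_{k+1})|$. Correctness is checked against the
brute-force-normalised posterior on the fully enumerable two-node space
(total-variation distance of the empirical distribution < 0.02). Defaults:
thinning 50, burn-in 10% of the iterations; the thinning counter advances
every iteration, accepted or not. A rejected proposal can never be a silent
self-transition because every move changes exactly one pair.

**Genetic algorithm.** A population of $p$ networks evolves by (1) selection
of the individuals scoring above the population median, truncated to the
best $\lfloor(1-q)p\rfloor$; (2) uniform edge-mask crossover within a random
fraction $q$ of the population ($\lceil qp\rceil$ individuals, paired; each
pair exchanges a random subset of ordered slots, so every offspring slot
comes from a parent); (3) single-edge mutation of $\lceil mp\rceil$
individuals — one uniformly chosen slot is reassigned to one of the two
*other* states, never a no-op. At the recommended $p=500$, $q=0.3$, $m=0.8$,
one generation processes 150 individuals in crossover and 400 in mutation.
The mutation bookkeeping follows the per-individual cost accounting (one
edge per mutated individual); the crossover operator and elitism — the
incumbent best network always survives unchanged, making the best score
monotone and testable — are package design decisions. Ties at the median
break by insertion order. Per generation, the log-likelihood and log-prior
differences of every changed individual to the population median are
recorded; for a well-calibrated Laplace prior the prior differences should
sit slightly above zero.

## Priors

**Laplace reference prior.** Given signed confidences
$B\in[-1,1]^{N\times N}$ (positive = activation belief, negative =
inhibition), each ordered pair contributes
$\Delta_{ij}=|\phi_{ij}-b_{ij}|^\gamma$ and the per-edge log prior
$-\log 2-\log\lambda-\Delta_{ij}/\lambda$; edges are a priori independent.
With type information $\Delta_{ij}\in[0,2^\gamma]$, so the per-edge density
lies between $\tfrac{1}{2\lambda}e^{-2^\gamma/\lambda}$ and
$\tfrac{1}{2\lambda}$; without it the signs of both $\Phi$ and $B$ are
dropped and $\Delta_{ij}\in[0,1]$. $\lambda$ (scale) controls sharpness:
in score *differences* the constant cancels, so the influence is carried by
$\Delta/\lambda$ — if likelihood differences along a chain are of order
$10^3$, set $\lambda=10^{-3}$ at $\gamma=1$ so a unit mismatch contributes
comparably. `ratioDiagnostics()` automates this check and suggests a
rescaling factor when the two dispersions differ by more than 10×. $\gamma$
(weight exponent) widens the plateau of tolerated small deviations near
$\Delta=0$.

`buildConfidenceMatrix()` aggregates a collection of signed reference
networks: per ordered pair, $b=(M_{act}-M_{inh})/M$ where $M$ counts the
references containing both nodes, zero for pairs seen in none. Conflicting
edge types across references are allowed and partially cancel.

**Scale-free prior.** For use when no edge confidences exist: node degrees
are assumed to follow a power law $P(d)\propto d^{-\gamma}$. The package
instantiates the construction as $P_i\propto i^{-\mu}$ with
$\mu=1/(\gamma-1)$, $\gamma\ge 2$ ($\gamma=2$, i.e. $\mu=1$, is accepted
with a warning); an ordered pair is unconnected with probability
$(1-P_iP_j)^{KN}$, the structure probability is the product over pairs
(signs ignored — only the degree structure matters), and the final value
averages the structure probability over random node permutations. The
permutations are drawn once, at prior construction (seeded), so that scores
are deterministic during sampling. Small $K$ prefers sparse structures.

## Simulation and evaluation

**Generator.** `sampleNetwork()` draws each ordered slot as an edge with
probability `edgeDensity` (default 0.2), inhibitory with probability
`pInhibition` (default 0.25); stimuli are the first `nStimuli` (default 2)
nodes with outgoing edges, and draws are repeated until every node is
reachable from the stimulus set. `simulateData()` propagates each
experiment's stimuli, stretches the state sequence uniformly over the $T$
time points and adds Gaussian noise. Defaults — $N=15$, $T=10$, $R=4$,
$\mu_p=0$, $\mu_a=2$, $\sigma=0.5$ — give a moderate signal-to-noise regime:
a 4-replicate time point separates the two means by $4\sigma$ standard
errors. Density, inhibition fraction and stimulus count are exposed, not
hard-coded, since realistic values vary by pathway. The generator emulates
state-driven Gaussian intensities with balanced replicates; it does not
emulate RPPA-specific artefacts (spatial effects, dilution series, missing
values), so passing tests speak to the inference machinery, not to
robustness against such artefacts.

**ROC/AUC.** Edge recovery is scored as a typed classification: every
ordered pair contributes an activation candidate and an inhibition
candidate, scored by the corresponding edge-type frequency in the sampled
collection (post-burn-in MCMC samples or the final GA population). A
candidate is a true positive only if direction *and* sign match the truth; a
sign mismatch is a false positive on the wrongly-signed candidate while the
true edge stays a false negative. Sweeping the inclusion threshold over the
observed frequencies traces the ROC; the AUC is the trapezoid area with
endpoints pinned at (0,0) and (1,1). This typed-candidate construction was
chosen over counting errors of the thresholded summary network because the
latter pushes a chance-level reconstruction well below AUC 0.5 (a random
sign hit is required for every true positive while sign misses inflate the
false positives), which would make chance-level and informative runs
incomparable on the usual scale; under the candidate view an uninformative
collection gives AUC 1/2 in expectation, a perfect one gives 1.

**Summaries, consensus, diagnostics.** `summariseNetworks()` keeps a typed
edge iff its frequency reaches the inclusion threshold (the more frequent
type wins a conflict; an exact activation/inhibition frequency tie breaks to
activation). `consensusNetwork()` merges per-chain summaries by majority
rule; exact ties go to the tied state with the larger posterior-frequency
average over the chains carrying it, which therefore requires the per-chain
frequency tables. `mcmcDiagnostics()` reports posterior traces,
per-chain signed edge counts and cross-chain edge-frequency variances,
flagging pairs above a variance threshold (default 0.05) — the pairs on
which chains disagree and a consensus edge deserves scepticism.

## Identifiability and limitations

Deterministic propagation makes some true edges observationally invisible:
an edge into a stimulus (clamped active) never affects the dynamics, and an
inhibition whose source is never active in any visited state leaves
$\Gamma$ unchanged. The likelihood cannot distinguish such a network from
the same network without the edge, and the BIC penalty then *prefers* the
smaller one. Reference priors are the practical remedy; without one, only
the dynamics-shaping core of a network is recoverable. Related limitations:
propagation is Boolean and synchronous (no graded or continuous-time
dynamics), missing values are not modelled, and the GA is an optimiser — it
concentrates its population near one optimum rather than sampling structure
uncertainty, and in our (and the original) experience it plateaus short of
a full reconstruction even under a strong prior.

## Reference problem sizes

The test suite and the acceptance script exercise the full pipeline at desk
scale, chosen so the whole suite runs in minutes while the behaviour of
interest is unambiguous: perfect-prior inhibMCMC at $N=8$ with
5,000–10,000 iterations (AUC reaches 1 at $\lambda=0.001$), perfect-prior
GA at $N=8$, $p=100$, 200 generations at $\lambda=0.01$ (AUC ≥ 0.95), and
prior-less BIC GA at $N=15$, $p=50$, 100 generations (chance-level AUC ≈
0.5, the failure mode that motivates prior knowledge). Production-scale
settings (50,000 MCMC iterations; $p\ge500$, 1,000 GA generations) are the
package defaults.

```{r example, eval = FALSE}
cfg <- simConfig(N = 8, seed = 1)
net <- sampleNetwork(cfg)
d <- simulateData(net, cfg)
prior <- laplacePrior(net, lambda = 0.001, gamma = 1)  # perfect prior
tr <- runMCMC(d, prior, nIter = 10000, burnin = 1000, thin = 50, seed = 2)
rocAuc(tr@networks, net)$auc
```
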