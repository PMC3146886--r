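# perturbNet

Inference of signed signalling networks — directed graphs with activation
(+1) and inhibition (−1) edges — from longitudinal high-throughput
measurements taken after external perturbation of network components, the
kind of data produced by time-resolved reverse-phase protein array (RPPA)
experiments on stimulated cell lines.

The underlying model is a dynamic deterministic effects propagation network
(DDEPN): a stimulus is clamped active and propagates through the signed
adjacency matrix Φ ∈ {0,1,−1}^(N×N) by a synchronous Boolean rule (active
iff ≥ 1 active activator and no active inhibitor), yielding an ordered
sequence of system states Γ. Measurements d_itr (protein i, time t,
replicate r) follow per-protein two-component Gaussians — active
N(μᵃᵢ, σᵃᵢ) vs passive N(μᵖᵢ, σᵖᵢ) — linked to Γ by a monotone time-to-state
assignment fitted with Viterbi training. Structures are searched either by

* **inhibMCMC** — Metropolis–Hastings structure sampling with six signed
  moves (add-activation, add-inhibition, delete, revert, switch-type,
  reverse-switch), candidates uniform over the neighbourhood N(Φ) so the
  proposal 1/|N(Φ)| needs (and gets) a Hastings correction, or
* a **genetic algorithm** — median-quantile selection, uniform edge-mask
  crossover and single-edge mutation with elitism,

optionally guided by a **Laplace reference prior** (per-edge log prior
−log 2 − log λ − Δᵢⱼ/λ with Δᵢⱼ = |φᵢⱼ − bᵢⱼ|^γ against signed confidences
B ∈ [−1,1]^(N×N)) or a **scale-free degree prior**. Simulation of ground
truth, threshold-sweep ROC/AUC edge-recovery evaluation, consensus-network
construction across chains and convergence diagnostics are included. See
`vignettes/network-inference.Rmd` for the full methods account.

## Worked example

Simulate a ground-truth network, hand the sampler the truth as a "perfect"
reference prior at strong weight (λ = 0.001), and measure edge recovery:

```r
library(perturbNet)

cfg <- simConfig(N = 8, seed = 1)          # 8 proteins, T = 10, R = 4
net <- sampleNetwork(cfg)
net
#> SignedNetwork: 8 nodes, 9 activation / 2 inhibition edges
#>   stimuli: X2, X4

d <- simulateData(net, cfg)
prior <- laplacePrior(net, lambda = 0.001, gamma = 1)
tr <- runMCMC(d, prior, nIter = 10000, burnin = 1000, thin = 50, seed = 11)
tr
#> McmcTrace: 10000 iterations, 180 thinned samples, acceptance rate 0.007

rocAuc(tr@networks, net)$auc
#> [1] 1
```

The AUC of 1 means the threshold-sweep ROC over the 180 post-burn-in
network samples recovers every true edge — direction and sign — before any
false one: with a perfect prior at λ = 0.001 a single edge mismatch costs
10³ on the log scale, so the chain is pinned to the reference. The low
acceptance rate is the flip side of that pinning. Raising λ loosens the
prior's grip (`ratioDiagnostics()` compares the likelihood and prior
movements to help choose λ); dropping the prior entirely replaces the
posterior with a BIC-penalised likelihood, which is where reconstruction
degrades to chance for larger networks.

A shell interface covering the same pipeline (`simulate`, `infer-mcmc`,
`infer-ga`, `build-prior`, `summarise`, `consensus`, `evaluate`,
`diagnose`) ships as `inst/scripts/perturbnet`; every run writes a
`manifest.json` with its resolved parameters, seed and input digests.

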