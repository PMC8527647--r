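---
title: "Designing sequences by stochastic activation maximization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sequences by stochastic activation maximization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastseqprop)
```

## The design problem

Given a differentiable fitness oracle $\mathcal{P}$ that maps an $N \times M$
one-hot sequence pattern to a scalar (a trained regulatory-activity model, a
structure predictor, or one of the toy landscapes shipped here), sequence
design is the optimization $\max_x \mathcal{P}(x)$ over discrete sequences.
Discreteness blocks plain gradient ascent, so the sequence is re-parameterized
by a trainable logit matrix $l \in \mathbb{R}^{N \times M}$:

* **pwm** — optimize the continuous relaxation $\sigma(l)$ (row-wise softmax)
  and read the design off the final probability matrix;
* **seqprop** — draw a discrete sample $\delta(l)$ per update, score it, and
  route the gradient through the softmax-straight-through (ST) estimator,
  which substitutes the softmax Jacobian
  $\partial\sigma_{ij}/\partial l_{ik} = \sigma_{ik}(\mathbb{1}_{j=k} - \sigma_{ij})$
  for the sampler's non-existent derivative;
* **fast_pwm / fast_seqprop** — the same two forward passes, but the logits
  are re-standardized at every update and passed through trainable scale and
  offset parameters $\gamma, \beta$ before the softmax.

The "fast" re-parameterization is the core of the package. Raw logits under
plain ascent drift to large, disproportionately scaled values where softmax
gradients vanish. Normalization pins their location and scale
($\mathrm{E}[l^{\text{(norm)}}] = 0$, $\mathrm{Var}[l^{\text{(norm)}}] = 1$),
and the scale parameter $\gamma$ becomes an adaptive inverse sampling
temperature: when sampled symbols with high confidence (large positive
normalized logit) also raise fitness, the $\gamma$ gradient is positive and
entropy drops (local refinement); inconsistent samples push $\gamma$ down and
re-open global exploration. `entropy_diagnostics()` exposes this trajectory.

Two normalization modes are provided. *Instance* normalization standardizes
each channel $j$ independently across positions — appropriate for nucleic
acids ($M = 4$), where per-channel composition biases are meaningful and each
channel has $N$ observations. *Layer* normalization standardizes all $N
\times M$ entries jointly with a single scalar $\gamma, \beta$ pair — the
default for proteins, where $M = 20$ channels over short sequences leave
per-channel statistics too noisy.

## Gradient conventions

No automatic differentiation framework is used: gradients flow through an
exact, modular reverse-mode chain of hand-derived vector–Jacobian products
(oracle input gradient → estimator backward → scale/offset → normalization).
Two conventions matter:

* **Normalization statistics are per-step constants.** The per-channel mean
  and standard deviation are recomputed at every forward pass but treated as
  constants in the backward pass, so
  $\partial l^{\text{(norm)}}_{ij} / \partial l_{ij} = 1/(\bar\varepsilon_j +
   10^{-6})$ with no cross-position terms. The backward chain then factorizes
  per entry into (estimator backward) × $\gamma_j$ × (inverse denominator),
  which is exactly the printed closed form implemented independently in
  `fast_seqprop_gradients_explicit()`; tests assert the two routes agree to
  machine precision, and the relaxed path is additionally checked against
  central finite differences.
* **Standard-deviation denominator.** The normalization divides the centered
  logits by the population standard deviation plus a $10^{-6}$ guard (constant
  channels map to zero). A published variant of the transform divides by the
  *variance*; that form breaks the unit-variance property, and we treat it as
  a typographical artifact, but `variance_denominator = TRUE` reproduces it
  for comparison.

Three estimators implement the discrete-to-continuous coupling
(`estimator()`): `softmax_st` (default; backward through the softmax Jacobian
at the same logits), `original_st` (identity backward), and `gumbel_softmax`
(hard forward sample via Gumbel-perturbed argmax, backward through the
tempered softmax of the perturbed logits; constant temperature, default 1.0
— no annealing schedule is applied).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `updates` (T) | 1000 | optimizer updates per run |
| `runs` (K) | 10 | independent restarts; the evaluation protocol reports losses over all K |
| `eval_samples` (S) | 10 | discrete samples per run for the test loss |
| `grad_samples` | 1 | samples averaged per gradient update |
| `learning_rate` | 0.02 | Adam step size |
| `init_r` | 1 | logits initialized i.i.d. uniform on $[-r, r]$ |
| `norm_mode` | instance | instance (DNA) or layer (protein) |
| gamma, beta init | 1, 0 | entropy parameters at the neutral point |

The optimizer is Adam with the standard moment defaults ($\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-7}$), implemented in-package. The step
size 0.02 is a displacement-budget choice: Adam moves each coordinate by
roughly the step size per update, long-horizon runs of this method family
use $\text{lr} \times T \approx 20$, and the desk-scale budgets here are
$T \approx 10^3$, giving 0.02. The train loss is
$-\mathcal{P}(x(l))$ with $x = \sigma(l)$ (relaxed methods) or $\delta(l)$
(sampled methods); the test loss is always
$-\frac{1}{KS}\sum_k\sum_s \mathcal{P}(\delta(l^{(k)})^{(s)})$, i.e. discrete
samples regardless of method, so relaxed methods cannot hide behind soft
inputs.

Each of the K runs reseeds R's RNG from `seed + 1000003 k`, making every run
reproducible and order-independent; the test-loss sampler is driven by the
same stream, so whole-design results are bit-reproducible under a fixed
configuration.

## Regularized objectives

`composite_objective()` folds penalty terms into a single oracle:

* **Likelihood margin** (`penalty_vae_margin()`):
  $\lambda \max(\log_{10} p_{\text{ref}} - \log_{10} p_{\text{model}}(x) -
  \rho, 0)$ keeps designs within a slack $\rho$ (log10 units) of the training
  data's reference likelihood $p_{\text{ref}}$. The shipped likelihood model
  is an exact factorized position-categorical (`make_factorized_likelihood()`),
  whose log-likelihood is linear in the one-hot pattern; latent-variable
  models supplied by users are expected to estimate $\log_{10} p$ by
  importance weighting (16 samples is a reasonable default) and expose the
  same two closures. Defaults: $\lambda = 1$, $\rho = 1$, $p_{\text{ref}}$ =
  mean model log10-likelihood of a provided training sample.
* **Probability of improvement** (`penalty_pi()`): for oracles predicting a
  fitness mean and standard deviation, maximize
  $\log_{10} \Pr_{\mathcal{N}(\mu,\epsilon)}(Y > q)$, computed from the
  log-scale normal survival function so extreme tails stay finite. The
  threshold default is the 95th percentile of scores on a provided sample.
* **Activity penalties** (`penalty_activity()`): $\sum_k \eta_k
  \max(\mathcal{C}_k(x) - C_k, 0)$ over user-supplied activation-map
  extractors.
* **Structure matching** (`kl_structure_loss()`): the mean KL divergence
  $\frac{1}{N^2}\sum_{ij}\sum_b Y_{ijb} \log(Y_{ijb}/X_{ijb})$ summed over
  the four geometry tensors (distance and three orientation angles), with the
  *target* as the weighting distribution $Y$ and the *prediction* as $X$ —
  the direction is pinned by a regression test. Natural logarithm;
  predictions floored at $10^{-8}$ before the ratio; $0 \log(0/\cdot) = 0$.
  All hinge penalties have exactly zero gradient in their inactive regions.

## Discrete-search baselines

*Evolution* mutates the current sequence with 1 or (with 50% probability) 2
random substitutions and accepts only strictly fitter candidates, so its
trajectory is non-decreasing; ties are rejected. *Simulated annealing* uses
single-substitution proposals under the Metropolis rule
$\min(1, e^{-(\mathcal{P}(x) - \mathcal{P}(x'))/T})$ with a geometric schedule
$T_t = T_0 \cdot d^t$ (defaults $T_0 = 1$, $d = 0.999$; no schedule is
canonical for this method family, and several initial temperatures are worth
trying). SA reports the best-so-far sequence rather than the final chain
state — the chain deliberately accepts downhill moves, so its last state is
not its best.

## What the synthetic fixtures emulate

The toy oracles stand in for trained predictors so every code path is
testable offline, covering three landscape classes: *separable* (linear
weights; positionwise argmax is the global optimum and enumeration is exact),
*epistatic* (smooth-max cross-correlation with a planted k-mer weight
pattern; overlapping placements compete), and *deceptive* (Hamming match to a
hidden target with an optional constant-fitness decoy plateau). The toy
structure predictor embeds each position's one-hot channels through fixed
random projections, pools ordered residue pairs additively, and emits
bin-softmax distribution tensors at the output shapes of real structure
predictors (37 distance bins; 24/24/12 angle bins), with a designated
solution sequence whose own output is the design target — so zero-loss
recovery is well-defined and the full KL path is exercised at true tensor
rank (desk scale, $N \le 50$).

What these fixtures do **not** emulate: the ruggedness, saturation and
out-of-distribution pathologies of trained deep networks, real data noise, or
predictor miscalibration. Passing tests therefore certify the optimization
machinery — estimator correctness, normalization behavior, convergence on
landscapes with known optima, ordering of method variants — not real-data
design performance, and the headline speedups reported for deep-net oracles
are deliberately out of scope here.

## Numerical choices and degenerate inputs

* Softmax rows are stabilized by row-max subtraction; `c(1000, 0, 0, 0)` maps
  to `c(1, 0, 0, 0)` without overflow.
* Constant channels (zero standard deviation) normalize to zero via the
  $10^{-6}$ guard rather than erroring.
* Argmax sequence extraction breaks ties to the lowest channel index;
  sampling needs no tie-break. Brute-force enumeration returns the
  lexicographically lowest maximizer and refuses spaces beyond $10^6$
  sequences.
* Non-finite logits, patterns, or losses abort with diagnostics (the design
  loop reports the run and update index).
* The design deliverable per run is both the argmax sequence of the final
  PSSM and S sampled sequences — which of the two is "the" design is left to
  the user, and both appear in the FASTA export.

## Problem sizes used by the test suite

The shipped tests run the full protocol at desk scale, chosen to keep the
whole suite in a few minutes of one CPU: linear-oracle recovery over 20
random $5 \times 4$ landscapes (1024-sequence enumerations) at $T = 1000$;
Hamming-target baselines at $N = 8$ (2000 greedy steps, 5000 annealing
steps); method-ordering comparisons on the motif landscape ($N = 30$, $T =
300$, $K = 10$) and the toy structure landscape ($N = 20$, $T = 200$, $K =
10$); and structure recovery at $N = 20$ with a KL threshold of 0.05 within
$T = 1000$, measured on the argmax sequence each update.

## Known limitations

* Multi-sample gradient averaging (`grad_samples` > 1) provably reduces
  per-update gradient variance (a paired test asserts this), but whether it
  shortens updates-to-threshold depends on the regime: under Adam's
  per-coordinate normalization on easy landscapes, convergence is
  displacement-bound and the medians can tie; the advantage shows mainly as
  tail robustness (fewer stalled runs) and in noise-dominated settings.
* Single-design optimization only: no batch normalization across simultaneous
  designs, no population-based search (GA/CMA-ES), no REINFORCE estimators.
* The factorized likelihood model is exact but cannot represent positional
  dependencies; it is a testing stand-in, not a generative model of real
  regulatory sequences.
* R-level loops put desk-scale problems in seconds-to-minutes territory;
  very long sequences (kilobases) against expensive oracles are better served
  by batched GPU implementations of the same algorithm.
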