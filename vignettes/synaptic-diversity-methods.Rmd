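---
title: "Synaptic-diversity training mechanisms: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synaptic-diversity training mechanisms: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastnn)
```

Biological neural networks are inhomogeneous and dynamic: synapses differ in
their plasticity, dendritic spines are spontaneously remodeled independent of
activity, and pairs of neurons are typically connected by several synapses
rather than one. `plastnn` implements three lightweight, drop-in training
mechanisms that carry these observations into ordinary gradient-descent
training of dense networks, plus the instruments used to evaluate them. This
vignette documents the models, their tunable parameters, the numerical
choices, and the limits of what the desk-scale experiments can show.

## The three mechanisms

### Fuzzy learning rates (FL)

Each trainable parameter $w_{n,i}$ receives a fixed multiplier
$\hat\eta_{n,i}$ sampled once at initialization, and the SGD update becomes

$$ w_{n,i,t+1} = w_{n,i,t} - \eta\, \nabla_{n,i} \odot \hat\eta_{n,i},
\qquad \hat\eta_{n,i} \sim \mathcal U\!\left(1-\tfrac\tau2,\ 1+\tfrac\tau2\right). $$

The *gradient scaling rate* $\tau$ (dimensionless, default 0.09; tuned
preset 0.5) is the width of the multiplier distribution; $\tau = 0$ recovers
plain SGD bit-exactly, and $\tau < 2$ keeps all multipliers positive so no
synapse trains "backwards". The field is immutable during a run — each
synapse has a *constant* individual learning speed, which is the point of
the model. Alternative sampling families (normal, lognormal, geometric,
beta) are provided; since no parameterization is canonical for them, each is
standardized to mean 1 and standard deviation $\tau/\sqrt{12}$ — the uniform
family's moments — so that $\tau$ has the same meaning across families.
Fields attach to all trainable arrays, weights and biases alike.

### Weight rejuvenation (WR)

Modeled on spontaneous spine remodeling, each weight is independently reset
to a fresh draw from its layer's initialization distribution, once per
optimizer step, with probability given by the Gaussian survival function of
its magnitude:

$$ P(\text{rejuvenate}) = 1 - \Phi\!\left(\frac{|w|}{\sigma_{re}}\right),
\qquad \sigma_{re} = \left|\frac{w_{\max}}{d_{re}}\right|, $$

where $w_{\max}$ is the layer's maximum absolute weight, recomputed at each
application, and $d_{re}$ is the *rejuvenation distance factor* (default
14; tuned preset 6). At $d_{re} = 1$ the largest weight is reset with
probability $1-\Phi(1) \approx 16\%$; at $d_{re} = 14$ the largest weight
essentially never resets while a weight of $0.02$ (with $w_{\max} = 1$)
resets with probability $1-\Phi(0.28) \approx 39\%$. (A survival probability
of 39% at weight $0.2$ would be inconsistent with the formula, which gives
0.26% there; the implementation and its tests use the $0.02$ reading, and
both readings are noted here deliberately.) The formula is evaluated on
$|w|$, not the signed weight: a signed upper limit would make large
*negative* weights near-certain to reset, contradicting the principle that
small weights are the volatile ones. Three further rules: a degenerate
all-zero layer uses the continuity limit $P = 0.5$ for every weight;
rejuvenation applies to weight matrices only (biases are zero-initialized
and have no spine analogue); and a rejuvenated weight keeps its FL
multiplier — the multiplier models the synapse's intrinsic plasticity, not
its current strength.

### Weight splitting (WS)

Modeled on multi-synaptic connectivity, a split layer with $N$ rows and
split factor $\Gamma$ forms only $N/\Gamma$ distinct outputs; distinct
output $n$ aggregates the rows $n + \gamma D$, $\gamma = 0,\dots,\Gamma-1$,
with block offset $D = \lfloor N/\Gamma \rfloor$:

$$ \phi_n = g\!\left(\sum_{\gamma=0}^{\Gamma-1}\sum_i
   w_{n+\gamma D,\,i}\, x_i \right), \qquad 0 \le n < N/\Gamma, $$

(synapse transfer is the identity, aggregation is the sum), after which the
distinct outputs are duplicated $\Gamma$ times so the layer keeps its output
width and its trainable parameter count — a true drop-in replacement. The
duplicated block is tiled contiguously, exactly matching the
$n + \gamma D$ index arithmetic of the aggregation; with $\Gamma = 1$ the
layer is bit-identical to a standard dense layer. An $N$ not divisible by
$\Gamma$ is a hard configuration error rather than a silent floor: the
orphaned rows would otherwise neither train nor contribute. Splitting
applies to hidden layers; the output layer keeps one synapse per logit.

## Trainer and evaluation protocol

The trainer is plain minibatch SGD (learning rate 0.01, cross-entropy for
classification, mean squared error for forecasting), with biases initialized
to exactly zero and weights from the fan-in-scaled uniform distribution
$\mathcal U(\pm 1/\sqrt{I})$, which is also the WR redraw distribution. Per
step: forward, backward, the (fuzzy) SGD update, then rejuvenation. With all
three toggles off the trajectory is bit-identical to a plain SGD reference —
this reduction is tested, and it is the reason every mechanism is
implemented as a pure array operation rather than woven into the update
loop.

Learning speed is measured retrospectively: training always runs the full
epoch budget, and `epochs_to_peak()` then returns the first epoch whose test
accuracy is not exceeded during the following `patience = 5` epochs (falling
back to the argmax for curves still rising at the end). The area under the
accuracy curve is reported as the *mean* per-epoch test accuracy: a
length-normalized AUC, comparable across runs of different lengths — the
unnormalized alternative would grow with the epoch budget and mean nothing
across protocols. Forecasting quality is NRMSE, the RMSE divided by the
population standard deviation of the ground truth over the evaluation
horizon, so a mean predictor scores exactly 1.

## Synthetic study conditions

The generators define the study conditions; they are fixed defaults, not
dials. The default classification task places 3 class means at the vertices
of a regular simplex with pairwise distance $4\sigma$ in 16 dimensions with
unit Gaussian noise, 900 samples, balanced labels: separable but noisy, with
a Monte-Carlo Bayes accuracy near 0.96, so a one-hidden-layer network (128
ReLU units, the desk-scale default; the 1000/3000-unit presets of the
full-scale protocol remain available through `hidden=`) learns it in tens of
epochs without saturating instantly. Data are split 2:1 (train statistics
only are used for normalization; three-fold concatenation-style
cross-validation is also provided) and trained for 40–50 epochs at batch
size 32 in the comparison experiments.

The chaotic benchmarks are the Thomas cyclically symmetric attractor
($\dot x = b\sin y - a x$ and cyclic permutations; $a = 1.85$, $b = 10$,
$dt = 2.882\times10^{-4}$) and the two-level Lorenz'96 system ($K = 36$
slow, $J = 10$ fast per slow, $b = c = 10$, $h = 1$, $dt = 0.1$; 396
dimensions). Two parameters are deliberate package choices: the Lorenz'96
forcing, unstated in the benchmark setting, defaults to $F = 10$, the
standard strongly chaotic regime; and the Thomas parameterization puts $b$
on the sinusoidal coupling, with both parameters exposed, because the
two-parameter setting cannot be mapped onto the canonical one-parameter
form — it is a documented reading, not an inference, and no quantitative
claim rests on it. Both systems are integrated with a fixed-step classical
RK4 scheme whose fourth-order convergence is verified in the tests; the
fast Lorenz'96 variables need sub-stepping (default 50 inner steps per
recorded sample) to stay in RK4's stability region, and 10% of the
requested samples are integrated and discarded as a transient before
recording. Default problem sizes throughout the tests are a few hundred to
a few thousand samples — large enough for the statistical checks, small
enough that the whole suite runs on one CPU in about a minute.

## Evaluation instruments

**Gradient inversion.** The attack is the classic gradient-matching
formulation: a dummy input is optimized so that the gradients it induces
match the observed ones in squared L2 distance (cosine distance available),
labels assumed known, batch size 1 by default — the cleanest and hardest
setting for the defense. The optimizer is adaptive-step gradient descent
with backtracking (accepted steps never increase the objective), with
central-finite-difference gradients of the matching objective with respect
to the dummy input; at desk-scale input sizes this is exact enough that the
attack recovers the closed-form single-layer inversion ($x = dW_i/db_i$) to
three digits, which is the test anchoring the attack's correctness. No
single attack recipe (matching objective, optimizer, label knowledge) is
canonical in the gradient-leakage literature; these defaults are this
package's documented choices. Reconstruction error is
$100\cdot\mathrm{MSE}(recon, target)/\mathrm{mean}(target^2)$ — 100% means
a difference as large as the target itself. Untrained networks are attacked
as well as trained ones, since their stronger gradients make inversion
easier and the defense claim correspondingly harder.

**Loss landscape.** `extreme_eigenvalues()` estimates the extreme Hessian
eigenvalues matrix-free: Hessian-vector products by central finite
differences of the analytic gradient (step
$\varepsilon = \sqrt{\epsilon_{mach}}\,(1+\lVert w\rVert)$), power
iteration with Rayleigh-quotient estimates for the dominant-magnitude
eigenvalue, then power iteration on the shifted operator
$H - \lambda_1 I$ for the opposite extreme. The shift route replaces the
classic Taylor-expansion/running-average scheme for the minimum eigenvalue;
both target the same extreme pair, and the shift method has the advantage
of being directly verifiable against a dense eigensolver, which the tests
do to 1% on random symmetric quadratics up to dimension 50. The MinMax
ratio is reported as $|\lambda_{\min}|/|\lambda_{\max}|$ — lower is more
convex — which keeps the ratio positive and scale-invariant even when
$\lambda_{\min} < 0$, as expected for non-convex losses.
`loss_surface()` evaluates the loss on a 2-D plane spanned by two seeded
random directions, rescaled per filter (per weight row, and per bias
vector) to match the parameter norms, so slices are comparable across
models; an odd grid size puts the unperturbed parameters exactly at the
center point. Non-convergence of the power iteration within `max_iter` is
flagged on the report, not thrown: on a landscape sweep a few slow points
should not abort the map.

## What the desk-scale experiments do and do not show

The acceptance-style experiments reproduce the *directions* of the headline
effects under the default mechanisms ($\tau = 0.09$, $d_{re} = 14$,
$\Gamma = 2$): no slower learning and no worse accuracy than baseline on
the blob task (means over 20 seeds; the per-seed early-stopping epoch has a
standard deviation of ~4.5 epochs, so smaller samples measure seed noise
rather than the effect), a higher median reconstruction error under weight
splitting, and stabilizing rejuvenation churn after the initial phase. They
do not — and cannot — reproduce full-scale benchmark numbers: Gaussian
blobs have none of the covariance structure, class imbalance, or spatial
statistics of natural images; the 128-unit MLP has no convolutions,
normalization, or residual paths; and several reported full-scale effects
(error-rate reductions on image benchmarks, NRMSE improvements with
recurrent and transformer models) depend on exactly those ingredients.
Passing tests here certify the mechanisms' implementations and the
direction of their effects under these synthetic conditions, nothing more.

## Worked example

```{r, eval = FALSE}
task <- make_classification_task(seed = 1)
splits <- prepare_splits(task$X, task$y, seed = 1)
baseline <- run_experiment(splits, config = train_config(epochs = 50, seed = 1))
biomod <- run_experiment(splits, config = train_config(
  epochs = 50, fl = TRUE, wr = TRUE, ws = TRUE, seed = 1
))
baseline
#> <train_result> 50 epochs, peak 0.9467 at epoch 11, auc 0.9347, 0 rejuvenations
biomod
#> <train_result> 50 epochs, peak 0.9567 at epoch 18, auc 0.9282, 1441 rejuvenations
```

## Known limitations

Only dense feed-forward networks are implemented; the mechanisms are
defined as pure array operations precisely so that convolutional or
recurrent integrations can reuse them, but none is provided. The trainer is
plain SGD — no momentum, Adam, or sharpness-aware variants — because the
mechanisms are defined relative to the plain SGD step and the reduction
identity is the package's central correctness anchor. The
finite-difference attack gradient scales linearly in the input dimension
and is impractical beyond a few hundred pixels. The Thomas parameter
mapping is a documented guess (see above). And the per-point landscape
spectra are expensive — quadratic in grid size times power-iteration cost —
so spectrum maps default to coarse grids.
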