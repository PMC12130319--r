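# plastnn

Biologically inspired synaptic-diversity mechanisms for neural-network
training, as a tested R toolkit.

Biological neural networks differ from artificial ones in three ways this
package models: synapses have *diverse plasticity* (they learn at different
speeds), dendritic spines undergo *spontaneous remodeling* (small synapses
are pruned and reformed independent of activity), and neuron pairs are
connected by *multiple synapses*. `plastnn` implements the corresponding
training mechanisms as pure array operations that drop into ordinary SGD:

- **Fuzzy learning rates (FL)** — a fixed per-parameter multiplier field
  `η̂ ~ U(1 − τ/2, 1 + τ/2)` applied to gradients:
  `w ← w − η (∇ ⊙ η̂)`. `τ = 0` recovers plain SGD bit-exactly.
- **Weight rejuvenation (WR)** — per step, each weight is reset to a fresh
  init draw with probability `1 − Φ(|w| / σ_re)`, `σ_re = |w_max / d_re|`:
  small weights churn, the largest essentially never (at the default
  `d_re = 14`).
- **Weight splitting (WS)** — each pair of neurons gets `Γ` synapses: output
  `n` of a layer aggregates weight rows `n + γ⌊N/Γ⌋`, and the `N/Γ` distinct
  outputs are duplicated `Γ` times, preserving output width and trainable
  parameter count.

Around the mechanisms the package provides what is needed to study them: an
explicit-backprop dense network and SGD trainer with retrospective
patience-5 early stopping; seedable generators for Gaussian-blob
classification tasks, procedural images, and the Thomas and two-level
Lorenz'96 chaotic systems (fixed-step RK4); a gradient-matching
**gradient-inversion attack** with the normalized reconstruction-error
metric (100% = difference as large as the target); and matrix-free
**Hessian extreme-eigenvalue** estimation with `|λ_min|/|λ_max|`
MinMax-ratio maps over filter-normalized 2-D loss surfaces.

Intended users: researchers in bio-inspired machine learning who want the
mechanisms as auditable primitives with their evaluation instruments, at a
scale that runs on one CPU.

## Worked example

```r
library(plastnn)

# the rejuvenation rule at its printed anchors
100 * rejuvenation_probability(w = 1,    w_max = 1, d_re = 1)   # 15.87  (~16%)
100 * rejuvenation_probability(w = 0.02, w_max = 1, d_re = 14)  # 38.97  (~39%)

# train baseline vs all three mechanisms on the default synthetic task
task   <- make_classification_task(seed = 1)   # 3 classes, 16 features, 900 samples
splits <- prepare_splits(task$X, task$y, seed = 1)
baseline <- run_experiment(splits, config = train_config(epochs = 50, seed = 1))
biomod   <- run_experiment(splits, config = train_config(
  epochs = 50, fl = TRUE, wr = TRUE, ws = TRUE, seed = 1))
baseline
#> <train_result> 50 epochs, peak 0.9467 at epoch 11, auc 0.9347, 0 rejuvenations
biomod
#> <train_result> 50 epochs, peak 0.9567 at epoch 18, auc 0.9282, 1441 rejuvenations
```

The printed line gives the early-stopping epoch (first epoch not improved
upon for 5 consecutive epochs), the test accuracy there, the mean per-epoch
test accuracy (normalized AUC), and the total number of rejuvenated weights.
Here the modified run reaches a higher peak accuracy (0.957 vs 0.947) while
rejuvenating ~1400 small weights over the run; single seeds are noisy, and
`run_comparison()` aggregates all 8 mechanism combinations over seed sets.

Privacy side effect, on an untrained network:

```r
net <- init_network(c(36, 8, 4), gamma = 2, seed = 1)     # split hidden layer
img <- make_image_task(n_samples = 1, side = 6, seed = 1) # secret batch
obs <- observe_gradients(net, img$X, img$y)
invert_gradients(net, obs, img$y, attack_config(seed = 1), target = img$X)
#> <reconstruction_report> objective 1.14, error 199.21%, 2 restart(s)
```

With `gamma = 1` the same attack typically drives the error to ~0% (perfect
reconstruction); with the split layer the reconstruction is worse than
guessing zero.

## Layout

- `R/` — mechanisms (`scale-field.R`, `rejuvenation.R`, `splitting.R`),
  network and trainer (`network.R`, `train.R`), generators (`synthdata.R`,
  `ode.R`), evaluation instruments (`inversion.R`, `landscape.R`), and the
  comparison/report layer (`compare.R`).
- `vignettes/synaptic-diversity-methods.Rmd` — models, parameters, numerical
  choices, and limitations.
- `inst/cli/plastnn` — thin command-line front-end
  (`train | compare | invert | landscape | simulate | report`).
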