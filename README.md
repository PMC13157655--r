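# choicernn

Biologically constrained recurrent networks for economic choice.

`choicernn` is an R package for studying how neural circuits can learn to
evaluate and compare offers. It trains excitatory–inhibitory recurrent
rate networks that obey Dale's law — with an actor policy and a critic
value readout from the same population — on a family of five trial-based
economic choice tasks (standard, risky, bundles, ternary, sequential)
using proximal policy optimization, and ships the analysis suite used to
dissect the trained circuits:

- **Behavior**: logistic / multinomial choice models estimating relative
  values `rho_hat` (reference good E fixed at 1), risk attitude
  `gamma_hat` (exponent on reward probability), choice consistency
  `eta_hat` and sequential order bias, by maximum likelihood.
- **Single neurons**: per-time-bin regressions of firing rates on decision
  variables (offer values, chosen value, choice, value sum/difference,
  conjunctive chosen values), two-step selectivity criteria
  (`p < 0.05`, `R^2 >= 0.005`), a temporal stability index, and
  categorical-vs-mixed coding via Delta-R^2 distributions.
- **Population geometry**: participation-ratio dimensionality
  `(sum lambda)^2 / sum lambda^2`, principal-component regression,
  pairwise subspace angles of rule-period activity, orthogonal Procrustes
  alignment across networks, task-variance clustering (k-means +
  silhouette) and fractional task variance.
- **Circuit mechanisms**: input-weight structure and selectivity index
  `(w_qC - w_qE)/(w_qC + w_qE)`, pooled (reduced) connectivity matrices
  and the competitive-recurrent-inhibition motif, SVD spectra,
  computational lesions (recurrent removal, clamping neuron groups), and
  a toy feedforward model of multiplicative value computation from ReLU
  ramp basis functions.

The offer model: an offer of good X is worth
`Value_X = rho_X * q_X * p_X`, with quantity `q_X ~ U(0, 10/rho_X)`,
probability `p_X ~ U(0, 1)` (1 in deterministic tasks), resampled until
`Value_X >= 1`. The network only ever sees quantities, probabilities and
cues — the intrinsic values `rho` must be learned from reward.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "choicernn", load_package = "installed")'
```

The suite validates every analysis on synthetic fixtures with planted
ground truth, checks the analytic BPTT gradient against finite
differences and an independent R implementation, and runs reduced-scale
training checks (see `tests/testthat/test-acceptance.R`).

## A worked example

The behavioral model is the bridge between choices and latent values.
Simulate 5,000 risky-task choices from known parameters and recover them
by maximum likelihood:

```r
library(choicernn)
set.seed(1)

d   <- simulate_choices("risky", 5000, rho_hat = list(C = 2),
                        gamma = 1.05, eta = 5)
fit <- fit_behavior(d, "risky")
fit
#> Behavioral fit (risky, n = 5000)
#>   rho: C=1.991
#>   gamma = 1.074  eta = 4.821  eps = 0.000  logLik = -1375.7
```

`rho_hat_C` near 2 recovers the relative value of good C against the
reference good E, `gamma_hat` near 1 is risk neutrality, and `eta_hat`
is the steepness of the psychometric function. The same fit applied to a
trained network's trial log reads out the values the circuit has learned
from reward alone.

Training a network end-to-end uses the same pieces:

```r
set.seed(1)
net <- init_network(network_config(n = 64))
res <- train_network(net, task_spec("standard"), cfg = ppo_config(),
                     total_steps = 2e7, eval_trials = 1000,
                     verbose = TRUE)
ev  <- evaluate_network(res$net, task_spec("standard"),
                        n_trials = 2000, log = TRUE)
fit <- fit_behavior(ev$trials, "standard")
```

Training passes through three phases — holding fixation, responding at
the go cue, then choosing by value — and the middle transition dominates
the budget (the methods vignette discusses its dynamics and failure
modes at reduced scale). From a trained network, `collect_rates()` +
`participation_ratio()` give the offer-period dimensionality,
`classify_selectivity()` the per-unit tuning, and the `circuit`
functions (`reduced_connectivity()`, `lesion_battery()`, ...) the
mechanism-level dissection.

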