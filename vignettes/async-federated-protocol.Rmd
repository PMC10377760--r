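---
title: "Asynchronous layer-split federated learning for cardiac risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asynchronous layer-split federated learning for cardiac risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedheart)
```

`fedheart` simulates a federation of hospitals that jointly train a
heart-disease risk model without sharing records. This vignette is the
package's account of the science: the model and protocol it implements,
the assumptions baked into each default, the numerical choices, and what
the simulator can and cannot tell you about real federated deployments.

## 1. The clinical schema and encoder

Records carry 16 attributes. Continuous measurements are discretised into
clinically interpretable bands with small integer codes centred near zero
(so the encoded features need no further scaling):

```{r}
default_schema()
```

Design notes on the encoder:

* **Band gaps.** The printed bands are not contiguous — chest-pain scores
  0.3–0.9, heart rates 69–70 and 90–91, cholesterol 239–240 fall between
  bands. Rather than invent new codes, the encoder assigns a gap value to
  the band whose nearest boundary is closest, with exact ties going to the
  lower band. This makes encoding total over the reals while agreeing with
  the printed code at every printed boundary.
* **Non-contiguous thallium codes.** The heart-status attribute keeps its
  conventional codes {3 = normal, 6 = fixed defect, 7 = reversible
  defect} verbatim; re-indexing them would break comparability with
  published encodings of this cohort family.
* **Strictness.** Categorical attributes accept labels only: passing the
  integer code 1 for sex is an error, not a silent pass-through. This
  catches double-encoding bugs at the boundary where they happen.
* **Files.** Datasets are plain CSV (comma, UTF-8, header, "." decimal)
  holding the integer codes; the schema itself serialises to YAML and
  round-trips identically. A fixed dialect keeps file-level tests
  bit-exact.

## 2. The synthetic cohort generator

No external data are required: `generate_dataset()` draws attribute codes
independently from per-attribute probability tables (uniform over each
attribute's legal codes unless configured) and then draws the disease
label from a logistic ground truth,

$$\Pr(y = 1 \mid x) = \mathrm{logit}^{-1}\!\Big(\beta_0 + \sum_a \beta_a
\,(x_a - \bar x_a)\Big),$$

flipped with probability `label_noise`. Effects act on codes centred at
their expected value $\bar x_a$, so $\beta_0$ is the prevalence logit of
the average patient — without centring, the always-positive thallium codes
would silently push prevalence towards 0.9.

Two cohort presets mimic datasets of different difficulty: `"DS1-like"`
(prevalence logit −0.2, 5% label noise) and `"DS2-like"` (+0.2, 15%
noise). Their shared effect vector weights the classical risk factors
(chest pain, angina, vessel count, ST slope, age at ±1–1.2 on the logit
scale; heart rate protective) and was calibrated once so that a federated
MLP reaches high-0.70s to low-0.80s test accuracy on a 303-record cohort —
the regime reported for real versions of this cohort — with the noisier
preset clearly harder. A third preset, `"separable"`, has a single
overwhelming effect (exercise-induced angina, ±10 logits) and no noise; it
is the sanity cohort on which any correctly wired learner must approach
perfect training accuracy.

What the generator deliberately does **not** emulate: correlated
attributes (real risk factors co-occur), missing values, site-specific
distribution shift between clients (the default split is IID), and
covariate-dependent label noise. Tests passing on these cohorts therefore
validate protocol mechanics and learner wiring, not clinical performance
on real registries. A `non_iid = TRUE` flag in `partition_clients()`
provides label-skewed shards for robustness exploration.

Arithmetic conventions, fixed for reproducibility: the held-out test size
is `round_half_up(fraction * n)` (303 records at 33% give 203 train / 100
test under either rounding convention, but the convention is pinned
anyway); client shards differ by at most one record, the remainder going
to the lowest-index clients (203 across 5 clients: 41/41/41/40/40).

## 3. Local learner

The federated object is a multilayer perceptron — default 16 and 8 tanh
hidden units, one sigmoid output — trained by full-batch gradient descent
on mean cross-entropy. This is the smallest learner that exercises a
deep/shallow parameter split; convolutional or recurrent architectures are
out of scope. Full-batch descent makes every run bit-reproducible, which
the protocol-equivalence tests exploit.

Defaults that matter (all exposed in `federation_config()`):

| parameter | default | units | why |
|---|---|---|---|
| `learning_rate` | 0.3 | logit/step | largest step that descends smoothly on 40-record shards |
| `epochs` | 5 | local steps/iteration | the conventional local-epoch count for federated averaging; 1 epoch under-converges 50-round runs |
| `hidden` | 16, 8 | units | small enough for 40-record clients, deep enough for a meaningful layer split |
| `alpha` | 0.5 | fraction of tensors | half the tensors (the output end) count as deep |
| `Delta` | 5 | iterations | deep group travels every 5th iteration |
| `L` | 50 | iterations | convergence horizon for all presets |
| `beta` | 1 | records | minimum data size to participate |
| `E` | 0.02 | loss | server stop threshold; effectively "run all L rounds" for these cohorts |

The deep group is the last $\lceil \alpha k \rceil$ of the $k$ parameter
tensors. The split is tensor-granular, not weight-granular: aggregation
then never has to reconcile partial tensors, and the two groups always
reconstruct the full collection exactly.

The RBF-kernel support-vector head
$D(x) = \sum_j \gamma_j e^{-\gamma_k \|x - d_j\|^2} + m_r$ is a *local*
decision layer: fitted on a node's own records (standard soft-margin dual
fitting via `e1071`, repackaged so the package's own `rsvm_decide()`
evaluates the decision form), never transmitted, and therefore free of
communication cost and privacy exposure. The conventional notation
overloads one symbol for both the support coefficients and the kernel
width; the implementation separates them (`coefficients` vs
`kernel_width`). The federated experiments use the MLP's sigmoid output
directly for classification; the kernel head is the optional
sharper-but-local alternative.

## 4. The protocol, and where it was genuinely open

**Client side.** Each of `Z` clients checks once, before its loop, whether
it holds at least `beta` records; under-resourced clients stay silent for
the whole run but still receive the final model. A participating client
runs `L` iterations: train locally, then upload the deep tensor group if
`l mod Delta == 0` (recording `l` in its timestep list and attaching a
block-log digest) and the shallow group otherwise. Every received global
model is logged append-only — iteration, parameter fingerprint, note —
with a logical clock rather than wall time, keeping runs byte-identical.
After iteration `L` the client's private data are purged; the purge is
idempotent, and any later attempt to train raises a dedicated error. That
purge-and-audit pair is the package's privacy contract: raw records never
leave the client object, and their deletion is enforced and testable, not
aspirational.

**Server side.** The server counts aggregation events (its `round_clock`),
and stops once the size-weighted global loss $\sum_i (A_i/A) f_i$ —
computed from client-*reported* losses, never from server-held data —
drops to `E`. A `max_updates` safety cap (default 500) bounds the loop,
since a loss threshold alone may never be reached.

Aggregation weights an update by `data size × staleness weight`, with the
staleness weight $(e/2)^{-s}$: 1 when fresh, strictly decaying as the
update's sender falls behind. An exponential-decay alternative
$e^{-\lambda s}$ is available by config.

Three questions the protocol's description leaves open, and the choices
made here:

* **Which clock defines staleness?** The client's iteration counter and
  the server's event counter are different clocks. Decision: staleness is
  server-side — events elapsed since the sender last received the global
  model — expressed on the federation-round scale (one round ≈ one arrival
  from each active client) so that the decay rate means the same thing at
  every federation size. The client's own timestep list γ_z is kept as the
  audit record of its deep exchanges.
* **How does a partial arrival meet the global model?** Two defensible
  policies are implemented. `blend = "contributors"` replaces each updated
  tensor by the pure convex combination of its contributors — the natural
  reading when every aggregation sees the whole federation, and the
  default for the standalone `aggregate_updates()` op. `blend = "global"`
  (the experiments' default) folds the batch into the current global
  tensor, `new = (1 − Σw)·old + Σ wᵢ·updateᵢ` with `wᵢ = sizeᵢ ×
  staleness_weightᵢ / total size`. The two coincide exactly whenever a
  full fresh batch arrives; they differ for lone arrivals, where pure
  replacement would make the global model ping-pong between client models
  and destroy learning. Both are config-selectable; the recursive blend is
  the default because per-arrival servers need it.
* **What does the downlink carry?** The broadcast mirrors the uplink: a
  client takes back the tensor group it just exchanged and keeps the other
  group evolving locally until that group's next exchange. Full
  replacement after every shallow exchange would reset each client's deep
  layers to a stale average every iteration, throttling deep-layer
  learning to one effective step per `Delta` iterations.

**Schedules.** `async_schedule()` assigns each client a lag factor;
client `z`'s `l`-th update arrives at time `l(1 + lag_z)`. The default is
all-zero lag: clients stay in lockstep and the *asynchrony is layerwise* —
deep and shallow groups travel on different schedules — which is the
protocol's core idea. Non-zero lags (`random_schedule()`) desynchronise
the client clocks; arrivals then come stale, the temporal weighting
becomes active, and accuracy degrades gracefully rather than
catastrophically. Arrivals sharing an arrival time are aggregated as one
batch; this is what makes the zero-delay, `Delta = 1`, `alpha = 1`
schedule collapse *exactly* (to 1e-10) onto the synchronous baseline — one
of the suite's oracle equivalences, alongside the single-client federation
matching centralized gradient descent and the synchronous average matching
an element-wise weighted-mean oracle.

## 5. Communication accounting

Costs are counted in transmitted scalar parameters and messages — not
bytes or seconds, which are hardware-bound. Over a full run a
participating client uploads

$$\lfloor L/\Delta \rfloor \cdot |{\rm deep}| + (L - \lfloor L/\Delta
\rfloor) \cdot |{\rm shallow}|$$

parameters against the synchronous baseline's $L \cdot P$. With the
default architecture on 15 features (417 parameters, deep group 153) and
`Delta = 5`, that is a 22.5% uplink saving. `communication_cost()` does
the arithmetic and, given a run's transmission trace, insists the two
reconcile exactly.

## 6. Evaluation

Metrics come from the confusion counts of the global model on the held-out
33% test split, positive class = disease: accuracy, precision, recall, and
F1 (the harmonic mean of precision and recall). Zero-denominator ratios
are reported as 0 and flagged rather than silently dropped.
`sweep_nodes()` repeats both protocols over federation sizes (2, 4, 6, 8,
10 by default) and renders a method × metric × size grid. Across that
sweep the simulator checks a *qualitative* claim only — that the
asynchronous protocol's accuracy does not deteriorate as the federation
grows — because absolute accuracies on the real cohorts depend on data and
training details no simulator can recover from a published table.

## 7. Numerical choices and degenerate inputs

* Sigmoid outputs are clipped to `[1e-12, 1 - 1e-12]` inside the
  cross-entropy, so separable data cannot produce infinite losses.
* `round_half_up` is used wherever a printed record count must be
  reproduced; R's default banker's rounding is avoided.
* Seeds: every stream (split, partition, init, per-iteration training)
  derives its own sub-seed from the master seed by hashing a salt string,
  so runs are reproducible end-to-end and sub-streams are decoupled. All
  derived seeds stay below 2^31.
* Parameter fingerprints (block logs, audit traces) are 31-bit rolling
  polynomial hashes over tensor shapes and IEEE-754 bytes — collisions are
  astronomically unlikely at this scale, and the hash is dependency-free.
* Degenerate inputs fail loudly: empty datasets, single-class kernel-head
  fits, shape-mismatched broadcasts, purged clients asked to train,
  aggregations with no updates, and causality violations (an update
  stamped in the server's future) all raise typed errors.

## 8. Problem sizes used by the test suite

The suite validates protocol mechanics at deliberately small scale:
cohorts of 80–400 records, federations of 1–10 clients, horizons of 3–50
iterations, and 10-replicate sweeps for the stochastic claims; the
marginal and prevalence checks use 10,000-record draws with 3-standard-
error bands. These sizes were chosen as the smallest at which each
property is non-trivial; everything is generated in code at test time.

## 9. Known limitations

* Simulated time is event-driven; there is no wall-clock, bandwidth or
  memory model, so hardware-bound comparisons are out of scope.
* No Byzantine robustness, secure aggregation, compression or
  differential privacy: the privacy property is structural (data never
  leave the client object; purge is enforced).
* Averaging tanh-network parameters is only meaningful between models that
  share an initialisation and stay aligned; the simulator inherits this
  standard limitation of federated averaging, which is visible in the
  accuracy cost of heavily lagged schedules.
* The generator's independence assumptions make its cohorts easier than
  real registries; absolute accuracies here calibrate the simulator, not
  clinical expectations.
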