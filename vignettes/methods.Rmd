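---
title: "Dual-branch neural matrix factorization: model, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch neural matrix factorization: model, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbdnmf)
```

# The completion problem

A drug sensitivity panel is a matrix `R` with one row per drug and one
column per cell line, holding a continuous response measurement (activity
area, where higher means more sensitive, or ln IC50, where lower does) for
the pairs that were actually screened. The package treats the observed
index set `Ω` and its complement as first-class objects: every model
quantity is defined relative to the binary mask `M`, and completion means
filling the cells with `M = 0`.

# Model

## Two branches over one weight stack

The model posits that the matrix is generated by a low-rank latent code
read out through both a linear and a nonlinear channel:

$$\hat R = \alpha\, f(D) + (1-\alpha)\, C \cdot D$$

where `D` (r × n, one column per cell line) is a *trainable input* — there
are no drug or cell-line features; the latent code is learned purely from
the observed responses. One stack of affine layers is evaluated twice:

* with tanh after every layer (including the output layer), giving the
  nonlinear reconstruction `f(D)`;
* with identity activations, giving an affine map whose zero-bias part is
  the ordered weight product `C = W^{(L+1)} \cdots W^{(1)}` — so the linear
  branch *is* a matrix factorization `C·D`, with `C` available in closed
  form via `implied_factor_matrix()`.

Sharing the stack is deliberate: the equations defining both branches use
the same weights, and the blend weight `α` then genuinely trades off two
readings of one parameterization rather than two separate models. For
ablation, `opts$tied_branches = FALSE` allocates an independent second
stack for the linear branch.

Because GER residuals (below) are roughly centred and of unit scale, a
tanh-bounded nonlinear branch is viable; the linear branch carries any
unbounded component. `opts$linear_output = TRUE` removes the output-layer
activation of the nonlinear branch for sensitivity checks.

Two networks are trained: the *column network* described above, and a *row
network* on the transposed matrix whose latent input is indexed by drugs.
Which headline orientation a real panel favours is an empirical matter, so
the default `side = "both_mean"` averages the two completions;
`"column_net"`/`"row_net"` reproduce single-orientation results such as
blend-weight sweeps per network.

## Loss

$$L = \frac{1}{2\eta}\,\bigl\lVert M \odot (R - \hat R)\bigr\rVert_F^2
  + \lambda\Bigl(\frac{1}{2n}\lVert D\rVert_F^2
  + \frac{1}{2}\sum_l \lVert W^{(l)}\rVert_F^2\Bigr)$$

with `η = |Ω|`, so the data term is a half *mean* squared error and `λ` is
comparable across matrix sizes. `α` appears in the training loss exactly as
in prediction, keeping the two consistent. Biases are not penalized.

## Global effect removal

Responses differ systematically by drug (potency, unit placement) and by
cell line (general chemosensitivity). GER decomposes

$$R = R_{global} + R_{drug} + R_{cell} + R_{res}$$

by sequential means over observed entries: the global mean first, then
per-drug (row) means of the remainder, then per-cell-line (column) means of
what is left. The decomposition is exact on observed entries by
construction (the package asserts reconstruction to 1e−10 relative), and
with incomplete masks the final residual has exactly zero column means
while row means are only approximately zero — the removal order fixes which
axis is exact. No shrinkage is applied to the effect estimates. Rows or
columns with no observations get effect 0, which is precisely the
cold-start fallback: a new drug is predicted from the global mean, the
cell-line effects and the latent structure shared with other drugs.

The networks are trained on `R_res`; predictions get the effects added
back. In cross-validation the effects are re-fit on each fold's training
entries only, so no information about hidden entries leaks through the
means.

# Optimization

Training is full-batch iRprop+ over every weight matrix, bias vector and
the latent input. Each scalar parameter carries its own step size:
agreement of successive gradient signs grows it by `η⁺`, a sign flip
shrinks it by `η⁻` and — the "+" part — if the loss also rose, the previous
update of that parameter is reverted before continuing. Because the update
depends only on gradient *signs*, the method is invariant to positive
rescaling of the loss and needs no global learning rate, which suits an
objective whose scale varies with `λ` and the data.

Constants default to `η⁺ = 1.2`, `η⁻ = 0.5`, `Δ_min = 10⁻⁶` — the customary
resilient-backpropagation values — with `Δ₀ = 0.0125` and `Δ_max = 1.0`
reduced to suit unit-scale residual data. Stopping: `max_epochs = 2000`, or
relative loss change below `rel_tol = 1e-6` for `patience = 5` consecutive
epochs.

**Initialization.** Weights are Gaussian with the Glorot standard deviation
`sqrt(2 / (fan_in + fan_out))`; the latent input starts at zero, so epoch 0
is the bias-only reconstruction. Biases start at zero rather than random:
this is standard practice, and it matters for cold starts — the output bias
of a fully held-out drug row receives no data gradient, so a random
initial value would survive training and contaminate exactly the
predictions a cold-start evaluation measures.

Exact gradients of the masked loss are derived by backpropagation through
both branches (both accumulate into the shared weights); the test suite
checks them against central finite differences over randomized
architectures to a 1e−5 relative tolerance.

# Defaults that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `rank` | 10 (4 in benchmarks) | latent dimensions | must be `< min(m, n)`; benchmark panels are generated at rank 4 |
| `hidden_sizes` | `c(4r, 2r)` | layer widths | tapering stack scaled to the rank |
| `alpha` | 0.5 | `[0, 1]` | equal linear/nonlinear shares; sweepable via `alpha_sweep()` |
| `lam` | 0.001 | penalty weight | see below |
| `use_ger` | `TRUE` | — | additive effects dominate raw panels |
| `side` | `both_mean` | — | average of the two orientations |
| `activation` | `tanh` | — | bounded, centred; suits GER residuals |

`lam` was chosen by inspecting training on the default synthetic benchmark:
because the penalty sums the squared Frobenius norms of *every* weight
matrix, `λ = 0.01` already makes it dominate the half-MSE data term on
unit-sd residuals — training stalls at a residual RMSE of ≈ 0.8 on data
with noise sd 0.1 — while `λ = 0.001` trains to near the noise floor and
still regularizes. This selection looked only at training behaviour, not at
any held-out target.

# The synthetic benchmark

`generate_synthetic()` draws exactly the structure the model assumes:
standard Gaussian factors `C*` (m × r) and `D*` (r × n); a nonlinear
component `f*(D*)` from a random tanh network (hidden width 8 by default,
with non-zero random biases so the component is not centred by
construction); the blend `α_true·f*(D*) + (1−α_true)·C*D*` rescaled to unit
standard deviation — so `noise_std` reads as a noise-to-signal ratio — plus
a constant global offset, Gaussian per-drug and per-cell-line effects, and
entrywise Gaussian noise. Masking hides an exact count of uniformly chosen
cells: exactly `round(observed_fraction · m · n)` entries remain observed.

The default condition is `m = 60, n = 40, r = 4, α_true = 0.5, noise sd 0.1,
70% observed`, with effect scales (offset 1, drug sd 0.5, cell sd 0.5) of
the same order as the unit signal — effects comparable to signal is what
motivates GER on real panels. Under this condition, 10-fold CV with the
default configuration reaches per-drug correlations above 0.95 and an
`ave_RMSE` several-fold below the per-drug-mean baseline (the acceptance
script recomputes the exact values).

What the generator does *not* emulate: the skewed, heavy-tailed marginals
of real activity-area/IC50 data, block-structured missingness (real GDSC
gaps cluster by screening batch), measurement error that correlates within
a drug, or any side information. Passing the recovery benchmarks therefore
demonstrates correctness of the machinery on data matching the model's
assumptions — not performance on any real panel.

# Evaluation conventions

Metrics are averaged per drug, so sparsely measured drugs weigh equally
with heavily measured ones. A drug enters the `ave_PCC` average only with
at least two evaluation entries and non-degenerate variance in both
vectors; it enters `ave_RMSE` with one. The two denominators can therefore
differ, and skipped drugs are reported explicitly. The
sensitive/resistant-restricted variants keep, per drug, the entries at or
beyond the first and third quartiles of that drug's evaluated responses
(type-7 interpolated quantiles; drugs with fewer than four entries keep
all). Top-k listings break ties by row order, deterministically.

For cold starts, metrics are computed per held-out unit (the drug's or cell
line's vector) and averaged over units.

# Numerical choices and degenerate inputs

* Fold assignment shuffles observed coordinates once with a seeded PRNG and
  deals round-robin: fold sizes never differ by more than one.
* A fold or split may hide a unit's every observation; this is never an
  error — the unit's latent column trains to the prior (zero) and its
  additive effect falls back to 0, mirroring a genuinely new drug.
* Non-finite losses abort training with the last finite model and a
  `"diverged"` status rather than an exception.
* All randomness flows through explicit integer seeds (`with_seed`
  restores the caller's RNG state); two runs with equal seeds are
  bit-identical.
* CSV round trips format values as `%.17g`, so written matrices re-read
  bit-exactly.

# Problem sizes used in the shipped checks

The test and acceptance suites run on simulated panels between 20 × 15 and
60 × 40 with rank 2–4 — large enough that the latent structure is
over-determined by the observations, small enough that the complete suite
runs in minutes on one core. The blend-weight sweep harness runs its full
9-point grid on both orientations at a reduced fold count (k = 2) on a
30 × 20 panel for the same reason; the full-`k` sweep on a larger panel is
a matter of CPU time, not of code paths.

# Known limitations

* Pure R; a panel of GDSC's size (295 × 969) trains in hours rather than
  minutes. The algorithm is full-batch by nature, so memory scales with
  `m·n`.
* No side information (drug structure, expression), which real cold-start
  prediction benefits from; a fully new drug is predicted mainly from the
  additive effects.
* `ave_PCC` of the two-network average is not guaranteed to dominate either
  single orientation; the default is a robustness choice, not an optimum.
* The quartile convention for `_sr` metrics uses each drug's *evaluated*
  entries, so CV and cold-start `_sr` values are not numerically comparable
  across different evaluation masks.
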