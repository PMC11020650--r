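#' Specification of a synthetic response matrix
#'
#' Describes the generative process the completion model assumes: a blended
#' linear/nonlinear low-rank signal, additive global/drug/cell-line effects,
#' Gaussian measurement noise, and uniform missingness. The low-rank signal
#' is rescaled to unit standard deviation before effects and noise are
#' added, so `noise_std` reads as a noise-to-signal ratio and the effect
#' scales are in signal units.
#'
#' Defaults describe the benchmark condition used throughout the package's
#' own evaluation: a 60 x 40 panel of rank 4, equal linear and nonlinear
#' signal shares, 10% noise, 70% of entries observed.
#'
#' @param m,n numbers of drugs and cell lines.
#' @param r true latent rank, `< min(m, n)`.
#' @param alpha_true share of the nonlinear component in the signal,
#'   in `[0, 1]`.
#' @param effect_global constant global offset added to every entry.
#' @param effect_drug_sd,effect_cell_sd standard deviations of the Gaussian
#'   per-drug and per-cell-line additive effects.
#' @param noise_std standard deviation of the entrywise Gaussian noise.
#' @param observed_fraction fraction of entries kept observed, in `(0, 1]`;
#'   masking is exact-count (exactly `round(observed_fraction * m * n)`
#'   cells observed).
#' @param hidden_sizes_true hidden widths of the random tanh network
#'   generating the nonlinear component.
#' @param seed integer seed; the whole draw is deterministic given it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 60L, n = 40L, r = 4L, alpha_true = 0.5,
                           effect_global = 1.0, effect_drug_sd = 0.5,
                           effect_cell_sd = 0.5, noise_std = 0.1,
                           observed_fraction = 0.7,
                           hidden_sizes_true = c(8L), seed = 20240404L) {
  m <- as.integer(m); n <- as.integer(n); r <- as.integer(r)
  if (r >= min(m, n)) stopf("need r < min(m, n)")
  if (!is_scalar_number(alpha_true) || alpha_true < 0 || alpha_true > 1) {
    stopf("`alpha_true` must be in [0, 1]")
  }
  if (!is_scalar_number(noise_std) || noise_std < 0) stopf("`noise_std` must be >= 0")
  if (!is_scalar_number(observed_fraction) || observed_fraction <= 0 || observed_fraction > 1) {
    stopf("`observed_fraction` must be in (0, 1]")
  }
  structure(list(m = m, n = n, r = r, alpha_true = alpha_true,
                 effect_global = effect_global,
                 effect_drug_sd = effect_drug_sd,
                 effect_cell_sd = effect_cell_sd,
                 noise_std = noise_std,
                 observed_fraction = observed_fraction,
                 hidden_sizes_true = as.integer(hidden_sizes_true),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic response matrix with retained ground truth
#'
#' Draws standard-Gaussian factor matrices `C` (m x r) and `D` (r x n),
#' pushes `D` through a random tanh network to obtain the nonlinear
#' component `f(D)`, blends `alpha_true * f(D) + (1 - alpha_true) * C D`,
#' rescales the blend to unit standard deviation, adds the additive effects
#' and entrywise Gaussian noise, and finally hides a uniformly random,
#' exact-count set of entries.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_truth`: list with `observed` (a
#'   [response_matrix()], noisy and masked), `full_matrix` (noise-free
#'   signal plus effects, fully observed), `signal` (noise-free, effect-free
#'   unit-sd blend), `C_true`, `D_true`, `effects_true` (a
#'   `global_effects`), `noise`, and `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) stopf("expected a `synthetic_spec`")
  with_seed(spec$seed, {
    C <- matrix(stats::rnorm(spec$m * spec$r), spec$m, spec$r)
    D <- matrix(stats::rnorm(spec$r * spec$n), spec$r, spec$n)
    gen_net <- network_params(spec$r, spec$hidden_sizes_true, spec$m,
                              activation = "tanh",
                              seed = stats::runif(1, 1, 2^30))
    # nonzero random biases so the nonlinear component is not centred by construction
    gen_net$biases <- lapply(gen_net$biases, function(b) stats::rnorm(length(b), sd = 0.5))
    f_D <- forward_nonlinear(gen_net, D)
    signal <- spec$alpha_true * f_D + (1 - spec$alpha_true) * (C %*% D)
    s <- stats::sd(as.numeric(signal))
    if (s > 0) signal <- signal / s
    drug_eff <- stats::rnorm(spec$m, sd = spec$effect_drug_sd)
    cell_eff <- stats::rnorm(spec$n, sd = spec$effect_cell_sd)
    full <- signal + spec$effect_global + outer(drug_eff, rep(1, spec$n)) +
      outer(rep(1, spec$m), cell_eff)
    noise <- matrix(stats::rnorm(spec$m * spec$n, sd = spec$noise_std), spec$m, spec$n)
    n_obs <- max(1L, round(spec$observed_fraction * spec$m * spec$n))
    obs_idx <- sample(spec$m * spec$n, n_obs)
    vals <- matrix(NA_real_, spec$m, spec$n)
    vals[obs_idx] <- (full + noise)[obs_idx]
    drug_ids <- sprintf("drug%03d", seq_len(spec$m))
    cell_ids <- sprintf("cell%03d", seq_len(spec$n))
    observed <- response_matrix(vals, drug_ids, cell_ids, unit_label = "synthetic")
    effects_true <- structure(list(global_mean = spec$effect_global,
                                   drug_effects = stats::setNames(drug_eff, drug_ids),
                                   cell_effects = stats::setNames(cell_eff, cell_ids)),
                              class = "global_effects")
    structure(list(observed = observed, full_matrix = full, signal = signal,
                   C_true = C, D_true = D, effects_true = effects_true,
                   noise = noise, spec = spec),
              class = "synthetic_truth")
  })
}

#' Simple imputation baselines on held-out entries
#'
#' Scores four reference imputations against the observed values at the
#' evaluation entries, using only the remaining observed (training) entries
#' to build each imputation: the global training mean, per-drug training
#' means, per-cell-line training means, and the additive global-effects
#' reconstruction (global + drug + cell-line effects fitted on the training
#' entries). These are the floor any latent-factor model must beat.
#'
#' @param st a `synthetic_truth` (or any list with an `observed`
#'   [response_matrix()]).
#' @param eval_mask 0/1 matrix choosing held-out entries; must be a subset
#'   of the observed mask and leave at least one training entry.
#' @return data frame with columns `method` and `rmse`.
#' @export
oracle_baselines <- function(st, eval_mask) {
  rm <- if (inherits(st, "response_matrix")) st else st$observed
  assert_response_matrix(rm)
  em <- (eval_mask != 0) * 1L
  if (sum(em) == 0L) stopf("`eval_mask` selects no entries")
  if (any(em == 1L & rm$mask == 0L)) stopf("`eval_mask` must select observed entries")
  train_rm <- mask_out_entries(rm, em == 1L)
  idx <- which(em == 1L)
  truth <- rm$values[idx]
  tv <- train_rm$values
  g <- mean(tv[train_rm$mask == 1L])
  row_mean <- rowMeans(tv, na.rm = TRUE); row_mean[is.nan(row_mean)] <- g
  col_mean <- colMeans(tv, na.rm = TRUE); col_mean[is.nan(col_mean)] <- g
  ge <- fit_global_effects(train_rm)
  preds <- list(
    global_mean = matrix(g, nrow(tv), ncol(tv)),
    per_drug_mean = matrix(row_mean, nrow(tv), ncol(tv)),
    per_cellline_mean = matrix(col_mean, nrow(tv), ncol(tv), byrow = TRUE),
    ger_additive = effects_matrix(ge, nrow(tv), ncol(tv))
  )
  data.frame(
    method = names(preds),
    rmse = vapply(preds, function(p) sqrt(mean((truth - p[idx])^2)), numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
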