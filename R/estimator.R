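#' Configuration for a dual-branch factorization fit
#'
#' Collects every tunable of the pipeline. Defaults follow common practice
#' for latent-factor completion of response panels; all are overridable.
#'
#' @param rank latent rank r (default 10); must be below `min(m, n)` of the
#'   matrix being fitted.
#' @param hidden_sizes hidden-layer widths; `NULL` (default) means
#'   `c(4 * rank, 2 * rank)`.
#' @param alpha nonlinear-branch blend weight in `[0, 1]` (default 0.5).
#' @param lam regularization weight (default 0.001; the penalty sums the
#'   squared Frobenius norms of every weight matrix, so values much larger
#'   than this overwhelm the half-mean-squared-error data term on
#'   unit-scale residuals).
#' @param use_ger fit and remove global/drug/cell-line effects before
#'   training and restore them on prediction (default `TRUE`).
#' @param side which network(s) to train: `"both_mean"` (default; average of
#'   the two completions), `"column_net"` (latent input indexed by cell
#'   lines) or `"row_net"` (latent input indexed by drugs, i.e. the
#'   transposed orientation).
#' @param activation nonlinearity of the nonlinear branch (default
#'   `"tanh"`).
#' @param opts optimizer/stopping options merged over the
#'   [train_network()] defaults.
#' @param seed integer seed; the column network uses `seed`, the row network
#'   `seed + 1`.
#' @return object of class `dbdnmf_config`.
#' @export
dbdnmf_config <- function(rank = 10L, hidden_sizes = NULL, alpha = 0.5,
                          lam = 0.001, use_ger = TRUE,
                          side = c("both_mean", "column_net", "row_net"),
                          activation = "tanh", opts = list(), seed = 1L) {
  side <- match.arg(side)
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) stopf("`alpha` must be in [0, 1]")
  if (!is_scalar_number(lam) || lam < 0) stopf("`lam` must be >= 0")
  rank <- as.integer(rank)
  if (rank < 1L) stopf("`rank` must be >= 1")
  if (is.null(hidden_sizes)) hidden_sizes <- c(4L * rank, 2L * rank)
  get_activation(activation)
  structure(list(rank = rank, hidden_sizes = as.integer(hidden_sizes),
                 alpha = alpha, lam = lam, use_ger = isTRUE(use_ger),
                 side = side, activation = activation, opts = opts,
                 seed = as.integer(seed)),
            class = "dbdnmf_config")
}

assert_config <- function(cfg) {
  if (!inherits(cfg, "dbdnmf_config")) stopf("expected a `dbdnmf_config` object")
  invisible(cfg)
}

#' Fit the dual-branch factorization model
#'
#' Optionally removes global effects, then trains the configured network(s)
#' on the (residual) matrix: the column network reconstructs the matrix from
#' a trainable latent input with one column per cell line; the row network
#' does the same on the transposed matrix, one latent column per drug.
#'
#' @param rm a [response_matrix()].
#' @param cfg a [dbdnmf_config()].
#' @return object of class `dbdnmf_model`: list with `config`, `effects`
#'   (`global_effects` or `NULL`), `column_model`, `row_model` (each a
#'   [train_network()] result or `NULL`), `drug_ids`, `cellline_ids`.
#' @export
dbdnmf_fit <- function(rm, cfg = dbdnmf_config()) {
  assert_response_matrix(rm)
  assert_config(cfg)
  if (cfg$rank >= min(dim(rm$values))) {
    stopf("rank (%d) must be below min(m, n) = %d", cfg$rank, min(dim(rm$values)))
  }
  effects <- NULL
  rm_work <- rm
  if (cfg$use_ger) {
    effects <- fit_global_effects(rm)
    rm_work <- remove_effects(rm, effects)
  }
  column_model <- NULL
  row_model <- NULL
  if (cfg$side %in% c("both_mean", "column_net")) {
    column_model <- train_network(rm_work, cfg$rank, cfg$hidden_sizes,
                                  cfg$alpha, cfg$lam, cfg$activation,
                                  cfg$opts, seed = cfg$seed)
  }
  if (cfg$side %in% c("both_mean", "row_net")) {
    row_model <- train_network(transpose_response(rm_work), cfg$rank,
                               cfg$hidden_sizes, cfg$alpha, cfg$lam,
                               cfg$activation, cfg$opts, seed = cfg$seed + 1L)
  }
  structure(list(config = cfg, effects = effects,
                 column_model = column_model, row_model = row_model,
                 drug_ids = rm$drug_ids, cellline_ids = rm$cellline_ids,
                 unit_label = rm$unit_label),
            class = "dbdnmf_model")
}

#' @export
print.dbdnmf_model <- function(x, ...) {
  parts <- c(if (!is.null(x$column_model)) "column" , if (!is.null(x$row_model)) "row")
  cat(sprintf("<dbdnmf_model> %d drugs x %d cell lines, rank %d, alpha %.2f, GER %s, nets: %s\n",
              length(x$drug_ids), length(x$cellline_ids), x$config$rank,
              x$config$alpha, if (x$config$use_ger) "on" else "off",
              paste(parts, collapse = "+")))
  invisible(x)
}

# Blended reconstruction of the full matrix (residual scale when GER is on).
model_prediction <- function(model) {
  cfg <- model$config
  preds <- list()
  if (!is.null(model$column_model)) {
    cm <- model$column_model
    preds$column <- predict_blend(cm$params, cm$Z, cfg$alpha, cm$params_linear)
  }
  if (!is.null(model$row_model)) {
    rmod <- model$row_model
    preds$row <- t(predict_blend(rmod$params, rmod$Z, cfg$alpha, rmod$params_linear))
  }
  Reduce(`+`, preds) / length(preds)
}

#' Complete a partially observed matrix with a fitted model
#'
#' Returns a fully observed matrix: observed entries keep their measured
#' values; unobserved entries are filled with the model's blended prediction
#' (averaged over the two networks when both were trained), mapped back to
#' the response scale when global effects were removed.
#'
#' @param model a fitted `dbdnmf_model`.
#' @param rm the [response_matrix()] to complete; its identifiers must match
#'   those the model was trained with.
#' @return a fully observed [response_matrix()].
#' @export
dbdnmf_complete <- function(model, rm) {
  if (!inherits(model, "dbdnmf_model")) stopf("expected a `dbdnmf_model`")
  assert_response_matrix(rm)
  if (!identical(rm$drug_ids, model$drug_ids) ||
      !identical(rm$cellline_ids, model$cellline_ids)) {
    stopf("matrix identifiers do not match the fitted model")
  }
  pred <- model_prediction(model)
  if (model$config$use_ger) pred <- restore_effects(pred, model$effects)
  vals <- rm$values
  fill <- rm$mask == 0L
  vals[fill] <- pred[fill]
  response_matrix(vals, rm$drug_ids, rm$cellline_ids, rm$unit_label)
}

#' k-fold cross-validation of the completion pipeline
#'
#' Partitions the observed entries into `k` folds; each fold in turn is
#' hidden (treated exactly like a missing entry, with global effects re-fit
#' on the remaining training entries only), the model is fitted on the rest
#' and the hidden entries are predicted. The per-fold test predictions are
#' assembled into one prediction matrix covering every observed entry;
#' entries missing from the start receive the average of the folds'
#' predictions but are never scored.
#'
#' @param rm a [response_matrix()].
#' @param cfg a [dbdnmf_config()].
#' @param k number of folds (default 10).
#' @param seed seed for the fold assignment; fold `f` trains with config
#'   seed `cfg$seed + 100 * f`.
#' @return list with `predictions` (numeric matrix), `overall` (a
#'   [metric_report()] over all observed entries), `fold_metrics` (data
#'   frame of per-fold ave_PCC/ave_RMSE and _sr variants) and `folds`.
#' @export
dbdnmf_cv <- function(rm, cfg = dbdnmf_config(), k = 10L, seed = 1L) {
  assert_response_matrix(rm)
  assert_config(cfg)
  fa <- assign_folds(rm, k, seed)
  pred <- matrix(NA_real_, nrow(rm$values), ncol(rm$values),
                 dimnames = dimnames(rm$values))
  miss_acc <- matrix(0, nrow(rm$values), ncol(rm$values))
  fold_rows <- vector("list", fa$k)
  for (f in seq_len(fa$k) - 1L) {
    test_idx <- which(!is.na(fa$fold) & fa$fold == f)
    rm_train <- mask_out_entries(rm, test_idx)
    cfg_f <- cfg
    cfg_f$seed <- cfg$seed + 100L * (f + 1L)
    model <- dbdnmf_fit(rm_train, cfg_f)
    comp <- dbdnmf_complete(model, rm_train)
    pred[test_idx] <- comp$values[test_idx]
    miss_acc <- miss_acc + comp$values * (rm$mask == 0L)
    em <- matrix(0L, nrow(rm$values), ncol(rm$values))
    em[test_idx] <- 1L
    rep_f <- metric_report(rm, comp$values, em)
    fold_rows[[f + 1L]] <- data.frame(fold = f, n_test = length(test_idx),
                                      ave_pcc = rep_f$ave_pcc,
                                      ave_rmse = rep_f$ave_rmse,
                                      ave_pcc_sr = rep_f$ave_pcc_sr,
                                      ave_rmse_sr = rep_f$ave_rmse_sr)
  }
  pred[rm$mask == 0L] <- miss_acc[rm$mask == 0L] / fa$k
  overall <- metric_report(rm, pred, rm$mask)
  list(predictions = pred, overall = overall,
       fold_metrics = do.call(rbind, fold_rows), folds = fa)
}

#' Cold-start (leave-one-unit-out) evaluation
#'
#' For every drug (or cell line) with observed entries, hides that entire
#' unit, refits the model on the remaining entries and scores the held-out
#' vector. The unit's own additive effect is unavailable to the refit and
#' falls back to zero, so predictions lean on the global mean, the other
#' axis's effects and the latent structure shared with the remaining units.
#'
#' @param rm a [response_matrix()].
#' @param cfg a [dbdnmf_config()].
#' @param axis `"drug"` or `"cellline"`.
#' @return list with `per_unit` (data frame: unit id, n_test, pcc, rmse,
#'   pcc_sr, rmse_sr) and `summary` (means over units, `NA`s dropped for
#'   pcc).
#' @export
cold_start_evaluate <- function(rm, cfg = dbdnmf_config(), axis = c("drug", "cellline")) {
  assert_response_matrix(rm)
  assert_config(cfg)
  axis <- match.arg(axis)
  splits <- cold_start_splits(rm, axis)
  rows <- vector("list", length(splits))
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    hidden <- rm$mask == 1L & sp$train_mask == 0L
    rm_train <- mask_out_entries(rm, hidden)
    cfg_s <- cfg
    cfg_s$seed <- cfg$seed + 100L * s
    model <- dbdnmf_fit(rm_train, cfg_s)
    comp <- dbdnmf_complete(model, rm_train)
    idx <- which(hidden)
    truth_v <- rm$values[idx]
    pred_v <- comp$values[idx]
    pcc <- if (length(idx) >= 2L && stats::sd(truth_v) > 0 && stats::sd(pred_v) > 0) {
      stats::cor(truth_v, pred_v)
    } else NA_real_
    rmse <- sqrt(mean((truth_v - pred_v)^2))
    # sensitive/resistant tails of this unit's true values
    if (length(idx) >= 4L) {
      q <- stats::quantile(truth_v, c(0.25, 0.75), type = 7, names = FALSE)
      keep <- truth_v <= q[1L] | truth_v >= q[2L]
    } else keep <- rep(TRUE, length(idx))
    tv <- truth_v[keep]
    pv <- pred_v[keep]
    pcc_sr <- if (length(tv) >= 2L && stats::sd(tv) > 0 && stats::sd(pv) > 0) {
      stats::cor(tv, pv)
    } else NA_real_
    rmse_sr <- sqrt(mean((tv - pv)^2))
    rows[[s]] <- data.frame(unit_id = sp$held_out_id, n_test = length(idx),
                            pcc = pcc, rmse = rmse, pcc_sr = pcc_sr,
                            rmse_sr = rmse_sr, stringsAsFactors = FALSE)
  }
  per_unit <- do.call(rbind, rows)
  summary <- list(ave_pcc = mean(per_unit$pcc, na.rm = TRUE),
                  ave_rmse = mean(per_unit$rmse),
                  ave_pcc_sr = mean(per_unit$pcc_sr, na.rm = TRUE),
                  ave_rmse_sr = mean(per_unit$rmse_sr),
                  n_units = nrow(per_unit))
  list(per_unit = per_unit, summary = summary)
}

#' Blend-weight (alpha) sweep
#'
#' Runs k-fold cross-validation at each alpha on the requested network
#' side(s) and tabulates ave_PCC/ave_RMSE, reproducing the design of the
#' classic sweep that locates the best linear/nonlinear compromise.
#'
#' @param rm a [response_matrix()].
#' @param cfg base [dbdnmf_config()]; its `alpha` and `side` are overridden.
#' @param alphas grid of blend weights (default `seq(0.1, 0.9, by = 0.1)`).
#' @param sides character vector of sides to evaluate (default
#'   `c("column_net", "row_net")`).
#' @param k folds per grid point (default 10).
#' @param seed fold-assignment seed.
#' @return data frame with columns `alpha`, `side`, `ave_pcc`, `ave_rmse`,
#'   `ave_pcc_sr`, `ave_rmse_sr`.
#' @export
alpha_sweep <- function(rm, cfg = dbdnmf_config(), alphas = seq(0.1, 0.9, by = 0.1),
                        sides = c("column_net", "row_net"), k = 10L, seed = 1L) {
  assert_response_matrix(rm)
  assert_config(cfg)
  rows <- list()
  for (side in sides) {
    for (a in alphas) {
      cfg_a <- cfg
      cfg_a$alpha <- a
      cfg_a$side <- side
      cv <- dbdnmf_cv(rm, cfg_a, k = k, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = a, side = side,
        ave_pcc = cv$overall$ave_pcc, ave_rmse = cv$overall$ave_rmse,
        ave_pcc_sr = cv$overall$ave_pcc_sr, ave_rmse_sr = cv$overall$ave_rmse_sr,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Save / load a fitted model
#'
#' The archive is a single RDS file holding the configuration, effects,
#' trained weight stacks and latent inputs.
#'
#' @param model a `dbdnmf_model`.
#' @param path archive path.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "dbdnmf_model")) stopf("expected a `dbdnmf_model`")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the `dbdnmf_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dbdnmf_model")) stopf("%s does not contain a dbdnmf model", path)
  model
}
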