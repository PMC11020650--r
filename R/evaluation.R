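# Per-drug evaluation of a completed matrix against held-out truth. All
# metrics are computed drug by drug over the entries flagged in an
# evaluation mask and then averaged across drugs, so a drug measured on many
# cell lines does not dominate one measured on few.

check_eval_inputs <- function(truth, pred, eval_mask) {
  assert_response_matrix(truth)
  if (!is.matrix(pred) || any(dim(pred) != dim(truth$values))) {
    stopf("`pred` must be a numeric matrix with the same shape as the truth")
  }
  if (!is.matrix(eval_mask) || any(dim(eval_mask) != dim(truth$values))) {
    stopf("`eval_mask` must be a matrix with the same shape as the truth")
  }
  em <- (eval_mask != 0) * 1L
  if (sum(em) == 0L) stopf("`eval_mask` selects no entries")
  if (any(em == 1L & truth$mask == 0L)) {
    stopf("`eval_mask` selects entries that are unobserved in the truth")
  }
  em
}

#' Per-drug averaged Pearson correlation
#'
#' For each drug (row), the Pearson correlation between true and predicted
#' values over that drug's evaluation entries; the headline value is the
#' mean over drugs. Drugs with fewer than 2 evaluation entries or zero
#' variance in either vector cannot yield a correlation and are excluded
#' from the average (and listed in `skipped`).
#'
#' @param truth a [response_matrix()] holding the measured values.
#' @param pred numeric matrix of predictions, same shape.
#' @param eval_mask 0/1 matrix marking the entries to score (must be a
#'   subset of the truth's observed mask).
#' @return list with `value` (the average), `per_drug` (named vector, `NA`
#'   for skipped drugs) and `skipped` (drug ids).
#' @export
ave_pcc <- function(truth, pred, eval_mask) {
  em <- check_eval_inputs(truth, pred, eval_mask)
  per <- rep(NA_real_, nrow(truth$values))
  names(per) <- truth$drug_ids
  for (i in seq_len(nrow(truth$values))) {
    j <- which(em[i, ] == 1L)
    if (length(j) < 2L) next
    x <- truth$values[i, j]
    y <- pred[i, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    per[i] <- stats::cor(x, y)
  }
  list(value = mean(per, na.rm = TRUE), per_drug = per,
       skipped = truth$drug_ids[is.na(per)])
}

#' Per-drug averaged RMSE
#'
#' For each drug, `sqrt(mean((truth - pred)^2))` over its evaluation
#' entries; averaged over drugs with at least one evaluation entry.
#'
#' @inheritParams ave_pcc
#' @return list with `value`, `per_drug`, `skipped`.
#' @export
ave_rmse <- function(truth, pred, eval_mask) {
  em <- check_eval_inputs(truth, pred, eval_mask)
  per <- rep(NA_real_, nrow(truth$values))
  names(per) <- truth$drug_ids
  for (i in seq_len(nrow(truth$values))) {
    j <- which(em[i, ] == 1L)
    if (length(j) == 0L) next
    per[i] <- sqrt(mean((truth$values[i, j] - pred[i, j])^2))
  }
  list(value = mean(per, na.rm = TRUE), per_drug = per,
       skipped = truth$drug_ids[is.na(per)])
}

#' Sensitive/resistant quartile mask
#'
#' Restricts an evaluation mask, per drug, to the entries whose true value
#' lies in the first or fourth quartile of that drug's evaluation values
#' (type-7 linear-interpolation quantiles): the most sensitive and most
#' resistant cell lines, the clinically decisive tails. Drugs with fewer
#' than 4 evaluation entries keep all of them (degenerate quartiles).
#'
#' @inheritParams ave_pcc
#' @return 0/1 matrix, a subset of `eval_mask`.
#' @export
sr_mask <- function(truth, eval_mask) {
  em <- check_eval_inputs(truth, truth$values, eval_mask)
  out <- em
  out[] <- 0L
  for (i in seq_len(nrow(truth$values))) {
    j <- which(em[i, ] == 1L)
    if (length(j) == 0L) next
    x <- truth$values[i, j]
    if (length(j) < 4L) {
      out[i, j] <- 1L
      next
    }
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    keep <- x <= q[1L] | x >= q[2L]
    out[i, j[keep]] <- 1L
  }
  out
}

#' Full metric report
#'
#' Convenience wrapper computing [ave_pcc()], [ave_rmse()] and their
#' sensitive/resistant-restricted variants in one call.
#'
#' @inheritParams ave_pcc
#' @return object of class `metric_report`: list with scalars `ave_pcc`,
#'   `ave_rmse`, `ave_pcc_sr`, `ave_rmse_sr`, a `per_drug` data frame
#'   (pcc, rmse, pcc_sr, rmse_sr, n_test per drug) and `skipped_drugs`.
#' @export
metric_report <- function(truth, pred, eval_mask) {
  em <- check_eval_inputs(truth, pred, eval_mask)
  srm <- sr_mask(truth, em)
  p <- ave_pcc(truth, pred, em)
  r <- ave_rmse(truth, pred, em)
  ps <- ave_pcc(truth, pred, srm)
  rs <- ave_rmse(truth, pred, srm)
  per <- data.frame(
    drug_id = truth$drug_ids,
    pcc = unname(p$per_drug), rmse = unname(r$per_drug),
    pcc_sr = unname(ps$per_drug), rmse_sr = unname(rs$per_drug),
    n_test = as.integer(rowSums(em)),
    stringsAsFactors = FALSE
  )
  structure(list(ave_pcc = p$value, ave_rmse = r$value,
                 ave_pcc_sr = ps$value, ave_rmse_sr = rs$value,
                 per_drug = per,
                 skipped_drugs = unique(c(p$skipped, ps$skipped))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> ave_PCC %.4f | ave_RMSE %.4f | ave_PCC_sr %.4f | ave_RMSE_sr %.4f (%d drugs)\n",
              x$ave_pcc, x$ave_rmse, x$ave_pcc_sr, x$ave_rmse_sr, nrow(x$per_drug)))
  invisible(x)
}

#' Top-k sensitive or resistant drugs per cell line
#'
#' Ranks the drugs for every cell line of a fully completed matrix and
#' reports each cell line's top-k list in the requested direction, plus a
#' frequency table of how often each drug appears across cell lines. The
#' measurement convention decides the sort: activity-area-like units are
#' `"higher_is_sensitive"`, ln IC50-like units are `"lower_is_sensitive"`.
#' Ties are broken by drug order in the matrix, deterministically.
#'
#' @param completed a fully observed [response_matrix()].
#' @param k list length, `<=` number of drugs.
#' @param direction `"sensitive"` or `"resistant"`.
#' @param sensitivity_convention `"higher_is_sensitive"` or
#'   `"lower_is_sensitive"`.
#' @return list with `lists` (data frame: cellline_id, rank, drug_id, value)
#'   and `frequency` (data frame: drug_id, count, percent, sorted by count).
#' @export
top_k_drugs <- function(completed, k,
                        direction = c("sensitive", "resistant"),
                        sensitivity_convention = c("higher_is_sensitive", "lower_is_sensitive")) {
  assert_response_matrix(completed)
  direction <- match.arg(direction)
  sensitivity_convention <- match.arg(sensitivity_convention)
  if (any(completed$mask == 0L)) stopf("`completed` must be fully observed")
  m <- nrow(completed$values)
  k <- as.integer(k)
  if (k < 1L || k > m) stopf("`k` must be between 1 and the number of drugs (%d)", m)
  # sensitive + higher_is_sensitive => descending; flips with either switch
  descending <- xor(direction == "resistant",
                    sensitivity_convention == "higher_is_sensitive")
  n <- ncol(completed$values)
  lists <- vector("list", n)
  for (j in seq_len(n)) {
    v <- completed$values[, j]
    ord <- order(if (descending) -v else v, seq_len(m))[seq_len(k)]
    lists[[j]] <- data.frame(cellline_id = completed$cellline_ids[j],
                             rank = seq_len(k),
                             drug_id = completed$drug_ids[ord],
                             value = v[ord],
                             stringsAsFactors = FALSE)
  }
  lists <- do.call(rbind, lists)
  counts <- table(factor(lists$drug_id, levels = completed$drug_ids))
  freq <- data.frame(drug_id = names(counts),
                     count = as.integer(counts),
                     percent = 100 * as.integer(counts) / n,
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$count, freq$drug_id), ]
  rownames(freq) <- NULL
  list(lists = lists, frequency = freq)
}
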