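#' Fit global effects (global / per-drug / per-cell-line means)
#'
#' Decomposes the observed entries of a response matrix into the additive
#' structure `R = global + drug_i + cell_j + residual`, estimated by
#' sequential mean removal in the style of the Netflix-prize "global
#' effects" baseline: first the global mean of all observed values, then the
#' per-drug (row) means of what is left, then the per-cell-line (column)
#' means of what is left after that. The decomposition is exact by
#' construction on the observed entries.
#'
#' Rows or columns with no observed entries receive effect 0, so cold-start
#' units fall back to the global mean plus the other axis's effect. No
#' shrinkage is applied to the per-axis means.
#'
#' @param rm a [response_matrix()].
#' @return an object of class `global_effects`: list with `global_mean`
#'   (scalar), `drug_effects` (length m), `cell_effects` (length n).
#' @export
fit_global_effects <- function(rm) {
  assert_response_matrix(rm)
  v <- rm$values
  g <- mean(v[rm$mask == 1L])
  centred <- v - g
  drug <- rowMeans(centred, na.rm = TRUE)
  drug[is.nan(drug)] <- 0 # all-missing row
  centred <- centred - drug
  cell <- colMeans(centred, na.rm = TRUE)
  cell[is.nan(cell)] <- 0
  structure(list(global_mean = g,
                 drug_effects = stats::setNames(as.numeric(drug), rm$drug_ids),
                 cell_effects = stats::setNames(as.numeric(cell), rm$cellline_ids)),
            class = "global_effects")
}

#' @export
print.global_effects <- function(x, ...) {
  cat(sprintf("<global_effects> global mean %.4g; %d drug effects (sd %.3g); %d cell-line effects (sd %.3g)\n",
              x$global_mean, length(x$drug_effects), stats::sd(x$drug_effects),
              length(x$cell_effects), stats::sd(x$cell_effects)))
  invisible(x)
}

assert_effects_match <- function(rm, ge) {
  if (!inherits(ge, "global_effects")) stopf("expected a `global_effects` object")
  if (length(ge$drug_effects) != nrow(rm$values) ||
      length(ge$cell_effects) != ncol(rm$values)) {
    stopf("effect dimensions (%d drugs, %d cell lines) do not match the matrix (%d x %d)",
          length(ge$drug_effects), length(ge$cell_effects),
          nrow(rm$values), ncol(rm$values))
  }
  invisible(TRUE)
}

effects_matrix <- function(ge, m, n) {
  ge$global_mean + outer(as.numeric(ge$drug_effects), rep(0, n), "+") +
    outer(rep(0, m), as.numeric(ge$cell_effects), "+")
}

#' Remove fitted global effects from a response matrix
#'
#' Subtracts `global + drug_i + cell_j` from every observed entry, leaving
#' the interaction residual. The mask and identifiers are unchanged.
#'
#' @param rm a [response_matrix()].
#' @param ge a `global_effects` object of matching dimensions.
#' @return a [response_matrix()] of residuals.
#' @export
remove_effects <- function(rm, ge) {
  assert_response_matrix(rm)
  assert_effects_match(rm, ge)
  vals <- rm$values - effects_matrix(ge, nrow(rm$values), ncol(rm$values))
  out <- response_matrix(vals, rm$drug_ids, rm$cellline_ids, rm$unit_label)
  stopifnot(identical(out$mask, rm$mask))
  out
}

#' Restore global effects onto a (residual or predicted) matrix
#'
#' Adds `global + drug_i + cell_j` to every entry, observed and predicted
#' alike; exact inverse of [remove_effects()] on observed entries. Accepts
#' either a `response_matrix` or a plain numeric matrix (as produced by the
#' network predictors for the unobserved cells).
#'
#' @param rm_res a [response_matrix()] or numeric matrix of residual values.
#' @param ge matching `global_effects`.
#' @return same type as `rm_res`, on the original response scale.
#' @export
restore_effects <- function(rm_res, ge) {
  if (is.matrix(rm_res) && is.numeric(rm_res)) {
    if (length(ge$drug_effects) != nrow(rm_res) || length(ge$cell_effects) != ncol(rm_res)) {
      stopf("effect dimensions do not match the matrix")
    }
    return(rm_res + effects_matrix(ge, nrow(rm_res), ncol(rm_res)))
  }
  assert_response_matrix(rm_res)
  assert_effects_match(rm_res, ge)
  vals <- rm_res$values + effects_matrix(ge, nrow(rm_res$values), ncol(rm_res$values))
  response_matrix(vals, rm_res$drug_ids, rm_res$cellline_ids, rm_res$unit_label)
}

#' Write global effects to a small CSV (three sections)
#'
#' @param ge a `global_effects` object.
#' @param path destination file.
#' @export
write_global_effects <- function(ge, path) {
  df <- data.frame(
    section = c("global", rep("drug", length(ge$drug_effects)),
                rep("cellline", length(ge$cell_effects))),
    id = c("global_mean", names(ge$drug_effects), names(ge$cell_effects)),
    effect = sprintf("%.17g", c(ge$global_mean, ge$drug_effects, ge$cell_effects)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read global effects written by [write_global_effects()]
#' @param path source file.
#' @return a `global_effects` object.
#' @export
read_global_effects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  eff <- as.numeric(df$effect)
  g <- eff[df$section == "global"][1L]
  d <- eff[df$section == "drug"]
  names(d) <- df$id[df$section == "drug"]
  cl <- eff[df$section == "cellline"]
  names(cl) <- df$id[df$section == "cellline"]
  structure(list(global_mean = g, drug_effects = d, cell_effects = cl),
            class = "global_effects")
}
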