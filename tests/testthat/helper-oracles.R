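# Fixtures and independent oracle implementations used across the suite.
# The oracles are deliberately naive (scalar loops, textbook formulas) so
# they share no code path with the package implementation.

make_random_rm <- function(m, n, n_missing = 0, seed = 1) {
  vals <- dbdnmf:::with_seed(seed, {
    v <- matrix(stats::rnorm(m * n), m, n)
    if (n_missing > 0) v[sample(m * n, n_missing)] <- NA
    v
  })
  response_matrix(vals)
}

# Network with non-trivial biases for gradient/forward checks.
make_random_params <- function(r, hidden, m, activation = "tanh", seed = 1,
                               linear_output = FALSE) {
  p <- network_params(r, hidden, m, activation = activation, seed = seed,
                      linear_output = linear_output)
  p$biases <- dbdnmf:::with_seed(seed + 99,
    lapply(p$biases, function(b) stats::rnorm(length(b), sd = 0.3)))
  p
}

oracle_act <- function(name) {
  switch(name,
    tanh = tanh,
    sigmoid = function(x) 1 / (1 + exp(-x)),
    relu = function(x) ifelse(x > 0, x, 0),
    identity = function(x) x)
}

# Column-by-column, layer-by-layer evaluation of the nonlinear branch.
loop_forward_nonlinear <- function(params, Z) {
  f <- oracle_act(params$activation)
  nL <- length(params$weights)
  out <- matrix(NA_real_, nrow(params$weights[[nL]]), ncol(Z))
  for (j in seq_len(ncol(Z))) {
    h <- Z[, j]
    for (l in seq_len(nL)) {
      a <- as.numeric(params$weights[[l]] %*% h) + params$biases[[l]]
      h <- if (l == nL && params$linear_output) a else f(a)
    }
    out[, j] <- h
  }
  out
}

loop_forward_linear <- function(params, Z) {
  nL <- length(params$weights)
  out <- matrix(NA_real_, nrow(params$weights[[nL]]), ncol(Z))
  for (j in seq_len(ncol(Z))) {
    h <- Z[, j]
    for (l in seq_len(nL)) h <- as.numeric(params$weights[[l]] %*% h) + params$biases[[l]]
    out[, j] <- h
  }
  out
}

# Scalar-summation re-implementation of the masked regularized loss.
loop_masked_loss <- function(params, Z, rm, alpha, lam) {
  Fm <- loop_forward_nonlinear(params, Z)
  G <- loop_forward_linear(params, Z)
  eta <- sum(rm$mask)
  acc <- 0
  for (i in seq_len(nrow(rm$values))) {
    for (j in seq_len(ncol(rm$values))) {
      if (rm$mask[i, j] == 1) {
        d <- rm$values[i, j] - alpha * Fm[i, j] - (1 - alpha) * G[i, j]
        acc <- acc + d * d
      }
    }
  }
  reg <- 0
  for (j in seq_len(ncol(Z))) reg <- reg + sum(Z[, j]^2)
  reg <- reg / (2 * ncol(Z))
  for (l in seq_along(params$weights)) reg <- reg + sum(params$weights[[l]]^2) / 2
  acc / (2 * eta) + lam * reg
}

# Textbook Pearson correlation (no stats::cor).
loop_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Central finite differences of masked_loss w.r.t. every parameter block.
fd_network_gradients <- function(params, Z, rm, alpha, lam, h = 1e-6) {
  fd_block <- function(get, set) {
    x <- get()
    g <- x
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      g[i] <- (masked_loss(set(xp), Z, rm, alpha, lam) -
               masked_loss(set(xm), Z, rm, alpha, lam)) / (2 * h)
    }
    g
  }
  dW <- list(); db <- list()
  for (l in seq_along(params$weights)) {
    dW[[l]] <- fd_block(function() params$weights[[l]],
                        function(x) {q <- params; q$weights[[l]] <- x; q})
    db[[l]] <- fd_block(function() params$biases[[l]],
                        function(x) {q <- params; q$biases[[l]] <- x; q})
  }
  dZ <- Z
  for (i in seq_along(Z)) {
    zp <- Z; zp[i] <- Z[i] + h
    zm <- Z; zm[i] <- Z[i] - h
    dZ[i] <- (masked_loss(params, zp, rm, alpha, lam) -
              masked_loss(params, zm, rm, alpha, lam)) / (2 * h)
  }
  list(weights = dW, biases = db, Z = dZ)
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(pmax(abs(a), abs(b)), floor))
}

grad_max_rel_err <- function(gr, fd) {
  errs <- c(
    vapply(seq_along(gr$weights), function(l) max_rel_err(gr$weights[[l]], fd$weights[[l]]), numeric(1)),
    vapply(seq_along(gr$biases), function(l) max_rel_err(gr$biases[[l]], fd$biases[[l]]), numeric(1)),
    max_rel_err(gr$Z, fd$Z))
  max(errs)
}

# Path to the installed CLI launcher; run it in a subprocess.
run_cli <- function(args) {
  script <- system.file("cli", "dbdnmf", package = "dbdnmf")
  out <- suppressWarnings(system2("Rscript", c(shQuote(script), args),
                                  stdout = TRUE, stderr = TRUE,
                                  env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
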