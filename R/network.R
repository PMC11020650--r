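# Dual-branch network: one stack of affine layers evaluated twice over a
# trainable latent input Z (r x n_cols) -- once with a nonlinear activation
# after every layer, once purely affine -- and blended by alpha. The same
# weight matrices serve both branches, which is what lets the linear branch's
# weight product play the role of the classical latent-factor matrix.

activation_fns <- list(
  tanh = list(f = tanh, df = function(a, h) 1 - h^2),
  sigmoid = list(f = stats::plogis, df = function(a, h) h * (1 - h)),
  relu = list(f = function(x) pmax(x, 0), df = function(a, h) (a > 0) * 1),
  identity = list(f = identity, df = function(a, h) array(1, dim(a)))
)

get_activation <- function(name) {
  if (!name %in% names(activation_fns)) {
    stopf("unknown activation '%s' (use one of: %s)", name,
          paste(names(activation_fns), collapse = ", "))
  }
  activation_fns[[name]]
}

#' Create a network parameter stack
#'
#' Builds the list of `L + 1` weight matrices and bias vectors mapping a
#' rank-`input_dim` latent input through hidden layers of the given sizes to
#' an `output_dim`-dimensional output (one output unit per drug for the
#' column-input network). Weights are drawn from a centred Gaussian with
#' Glorot standard deviation `sqrt(2 / (fan_in + fan_out))`; biases start at
#' zero.
#'
#' @param input_dim latent rank r (rows of the latent input).
#' @param hidden_sizes integer vector of hidden-layer widths (may be empty
#'   for a single affine layer, the plain matrix-factorization case).
#' @param output_dim number of output units (matrix rows being reconstructed).
#' @param activation nonlinearity of the nonlinear branch: `"tanh"`
#'   (default), `"sigmoid"`, `"relu"` or `"identity"`.
#' @param seed integer seed for the weight draws.
#' @param linear_output if `TRUE` the nonlinear branch's output layer is
#'   affine (no activation); default `FALSE` applies the activation at the
#'   output too.
#' @return object of class `network_params`: list with `weights`, `biases`,
#'   `activation`, `linear_output`, `dims`.
#' @export
network_params <- function(input_dim, hidden_sizes, output_dim,
                           activation = "tanh", seed = 1L,
                           linear_output = FALSE) {
  get_activation(activation)
  dims <- c(as.integer(input_dim), as.integer(hidden_sizes), as.integer(output_dim))
  if (any(dims < 1L)) stopf("all layer dimensions must be >= 1")
  n_layers <- length(dims) - 1L
  if (n_layers < 1L) stopf("need at least one layer")
  with_seed(seed, {
    weights <- vector("list", n_layers)
    biases <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      fan_in <- dims[l]
      fan_out <- dims[l + 1L]
      sd <- sqrt(2 / (fan_in + fan_out))
      weights[[l]] <- matrix(stats::rnorm(fan_out * fan_in, sd = sd), fan_out, fan_in)
      biases[[l]] <- numeric(fan_out)
    }
    structure(list(weights = weights, biases = biases, activation = activation,
                   linear_output = isTRUE(linear_output), dims = dims),
              class = "network_params")
  })
}

#' Create a latent input matrix
#'
#' The trainable low-rank input fed to the network: one column per unit being
#' reconstructed against (cell lines for the column-input network, drugs for
#' the transposed one). Initialized to zero, the convention under which
#' training starts from the bias-only reconstruction.
#'
#' @param r latent rank.
#' @param n_cols number of columns.
#' @param init `"zero"` (default) or `"gaussian"` (sd `1/sqrt(r)`).
#' @param seed seed used when `init = "gaussian"`.
#' @return object of class `latent_input`: list with `Z` (r x n_cols) and `r`.
#' @export
latent_input <- function(r, n_cols, init = c("zero", "gaussian"), seed = 1L) {
  init <- match.arg(init)
  r <- as.integer(r)
  n_cols <- as.integer(n_cols)
  if (r < 1L) stopf("latent rank must be >= 1")
  Z <- if (init == "zero") {
    matrix(0, r, n_cols)
  } else {
    with_seed(seed, matrix(stats::rnorm(r * n_cols, sd = 1 / sqrt(r)), r, n_cols))
  }
  structure(list(Z = Z, r = r), class = "latent_input")
}

as_latent <- function(Z) {
  if (inherits(Z, "latent_input")) return(Z)
  if (is.matrix(Z)) return(structure(list(Z = Z, r = nrow(Z)), class = "latent_input"))
  stopf("expected a `latent_input` or a matrix")
}

check_dims <- function(params, Z) {
  if (nrow(Z) != params$dims[1L]) {
    stopf("latent input has %d rows but layer 1 expects %d", nrow(Z), params$dims[1L])
  }
}

# Full forward pass through the nonlinear branch keeping the per-layer
# pre-activations and outputs (needed for backprop).
forward_nonlinear_trace <- function(params, Z) {
  check_dims(params, Z)
  act <- get_activation(params$activation)
  n_layers <- length(params$weights)
  pre <- vector("list", n_layers)
  post <- vector("list", n_layers)
  h <- Z
  for (l in seq_len(n_layers)) {
    a <- params$weights[[l]] %*% h + params$biases[[l]]
    is_out <- (l == n_layers)
    h <- if (is_out && params$linear_output) a else act$f(a)
    pre[[l]] <- a
    post[[l]] <- h
  }
  list(pre = pre, post = post, output = h)
}

forward_linear_trace <- function(params, Z) {
  check_dims(params, Z)
  n_layers <- length(params$weights)
  post <- vector("list", n_layers)
  h <- Z
  for (l in seq_len(n_layers)) {
    h <- params$weights[[l]] %*% h + params$biases[[l]]
    post[[l]] <- h
  }
  list(post = post, output = h)
}

#' Nonlinear branch forward pass
#'
#' Applies every affine layer followed by the configured activation:
#' `h^(l) = sigma(W^(l) h^(l-1) + b^(l))`, starting from the latent input.
#' Biases broadcast across columns.
#'
#' @param params a [network_params()].
#' @param Z a [latent_input()] or plain matrix with `r` rows.
#' @return numeric matrix, `output_dim` x `n_cols`.
#' @export
forward_nonlinear <- function(params, Z) {
  forward_nonlinear_trace(params, as_latent(Z)$Z)$output
}

#' Linear branch forward pass
#'
#' The same layer stack traversed with all activations replaced by the
#' identity, i.e. a composition of affine maps.
#'
#' @inheritParams forward_nonlinear
#' @return numeric matrix, `output_dim` x `n_cols`.
#' @export
forward_linear <- function(params, Z) {
  forward_linear_trace(params, as_latent(Z)$Z)$output
}

#' Implied linear factor matrix
#'
#' The ordered product of all weight matrices, output side first:
#' `W^(L+1) W^(L) ... W^(1)`. With zero biases the linear branch equals this
#' matrix times the latent input, so it is the learned latent-factor matrix
#' of the classical factorization reading of the model.
#'
#' @param params a [network_params()].
#' @return `output_dim` x `input_dim` matrix.
#' @export
implied_factor_matrix <- function(params) {
  Reduce(`%*%`, rev(params$weights))
}

#' Blended dual-branch prediction
#'
#' `alpha * forward_nonlinear + (1 - alpha) * forward_linear`: the model's
#' reconstruction of the full matrix, from which the caller takes the
#' unobserved cells.
#'
#' @inheritParams forward_nonlinear
#' @param alpha blend weight of the nonlinear branch, in `[0, 1]`.
#' @param params_linear optional second `network_params` used for the linear
#'   branch when the branches are untied; default `NULL` shares `params`.
#' @return numeric matrix, `output_dim` x `n_cols`.
#' @export
predict_blend <- function(params, Z, alpha, params_linear = NULL) {
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) {
    stopf("`alpha` must be a single number in [0, 1]")
  }
  Zm <- as_latent(Z)$Z
  lin_params <- if (is.null(params_linear)) params else params_linear
  alpha * forward_nonlinear_trace(params, Zm)$output +
    (1 - alpha) * forward_linear_trace(lin_params, Zm)$output
}

#' Masked regularized training loss
#'
#' Half mean squared error of the blended reconstruction over the observed
#' entries, plus a quadratic penalty on the latent input and the weights
#' (biases unpenalized):
#' \deqn{L = \frac{1}{2\eta}\lVert M \odot (R - \alpha f(Z) - (1-\alpha)\,\mathrm{lin}(Z))\rVert_F^2
#'   + \lambda\Big(\frac{1}{2n}\lVert Z\rVert_F^2 + \frac12\sum_l \lVert W^{(l)}\rVert_F^2\Big)}
#' where `eta` is the number of observed entries and `n` the number of
#' columns of `Z`.
#'
#' @inheritParams predict_blend
#' @param rm a [response_matrix()] whose rows match the output dimension and
#'   whose columns match the latent input's columns.
#' @param lam regularization weight `lambda >= 0`.
#' @return scalar loss.
#' @export
masked_loss <- function(params, Z, rm, alpha, lam, params_linear = NULL) {
  assert_response_matrix(rm)
  if (!is_scalar_number(lam) || lam < 0) stopf("`lam` must be a single number >= 0")
  Zm <- as_latent(Z)$Z
  if (ncol(rm$values) != ncol(Zm)) {
    stopf("matrix has %d columns but latent input has %d", ncol(rm$values), ncol(Zm))
  }
  pred <- predict_blend(params, Zm, alpha, params_linear)
  if (nrow(pred) != nrow(rm$values)) {
    stopf("network output has %d rows but matrix has %d", nrow(pred), nrow(rm$values))
  }
  eta <- sum(rm$mask)
  resid <- rm$values - pred
  resid[rm$mask == 0L] <- 0
  data_term <- frob2(resid) / (2 * eta)
  lin_params <- if (is.null(params_linear)) params else params_linear
  w_pen <- sum(vapply(params$weights, frob2, numeric(1L)))
  if (!is.null(params_linear)) {
    w_pen <- w_pen + sum(vapply(lin_params$weights, frob2, numeric(1L)))
  }
  reg <- frob2(Zm) / (2 * ncol(Zm)) + w_pen / 2
  data_term + lam * reg
}

# Backprop through one activation stack. delta_out is dL/d(output).
# Returns gradients for that stack's weights/biases plus dL/dZ.
backprop_stack <- function(params, Zm, trace, delta_out, nonlinear) {
  act <- get_activation(params$activation)
  n_layers <- length(params$weights)
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  delta <- delta_out
  for (l in rev(seq_len(n_layers))) {
    if (nonlinear) {
      is_out <- (l == n_layers)
      if (!(is_out && params$linear_output)) {
        delta <- delta * act$df(trace$pre[[l]], trace$post[[l]])
      }
    }
    h_prev <- if (l == 1L) Zm else trace$post[[l - 1L]]
    dW[[l]] <- delta %*% t(h_prev)
    db[[l]] <- rowSums(delta)
    delta <- t(params$weights[[l]]) %*% delta
  }
  list(dW = dW, db = db, dZ = delta)
}

#' Exact gradients of the masked loss
#'
#' Backpropagates through both branches: the nonlinear branch contributes
#' `alpha` times its chain, the linear branch `(1 - alpha)` times its affine
#' chain, and (with tied branches) both accumulate into the same weight and
#' bias gradients. The latent input receives both branches' input gradients
#' plus its `lambda Z / n` penalty gradient.
#'
#' @inheritParams masked_loss
#' @return list with `weights` and `biases` (lists of gradient arrays
#'   matching `params`), `Z` (gradient matrix), and, when `params_linear` is
#'   supplied, `weights_linear` and `biases_linear`.
#' @export
network_gradients <- function(params, Z, rm, alpha, lam, params_linear = NULL) {
  assert_response_matrix(rm)
  if (!is_scalar_number(lam) || lam < 0) stopf("`lam` must be a single number >= 0")
  if (!is_scalar_number(alpha) || alpha < 0 || alpha > 1) {
    stopf("`alpha` must be a single number in [0, 1]")
  }
  Zm <- as_latent(Z)$Z
  lin_params <- if (is.null(params_linear)) params else params_linear
  tr_nl <- forward_nonlinear_trace(params, Zm)
  tr_li <- forward_linear_trace(lin_params, Zm)
  pred <- alpha * tr_nl$output + (1 - alpha) * tr_li$output
  eta <- sum(rm$mask)
  E <- pred - rm$values
  E[rm$mask == 0L] <- 0
  E <- E / eta # dL/d(pred)
  g_nl <- backprop_stack(params, Zm, tr_nl, alpha * E, nonlinear = TRUE)
  g_li <- backprop_stack(lin_params, Zm, tr_li, (1 - alpha) * E, nonlinear = FALSE)
  dZ <- g_nl$dZ + g_li$dZ + lam * Zm / ncol(Zm)
  if (is.null(params_linear)) {
    dW <- mapply(function(a, b, w) a + b + lam * w,
                 g_nl$dW, g_li$dW, params$weights, SIMPLIFY = FALSE)
    db <- mapply(`+`, g_nl$db, g_li$db, SIMPLIFY = FALSE)
    list(weights = dW, biases = db, Z = dZ)
  } else {
    dW <- mapply(function(a, w) a + lam * w, g_nl$dW, params$weights, SIMPLIFY = FALSE)
    dWl <- mapply(function(a, w) a + lam * w, g_li$dW, lin_params$weights, SIMPLIFY = FALSE)
    list(weights = dW, biases = g_nl$db,
         weights_linear = dWl, biases_linear = g_li$db, Z = dZ)
  }
}
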