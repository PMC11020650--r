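# Full-batch iRprop+ (resilient backpropagation with weight backtracking).
# Parameters are handled as a flat named list of numeric arrays; the step
# rule is elementwise and depends only on gradient signs, so it is invariant
# to positive rescaling of the loss.

#' iRprop+ hyperparameters and state
#'
#' Creates the per-parameter state for [irprop_plus_step()]: an individual
#' step size for every scalar parameter (all starting at `delta0`), the
#' previous gradient and previous applied update (zero), and the previous
#' loss (`+Inf`, so the first step can never trigger a backtrack).
#'
#' @param theta named list of numeric arrays (the trainable parameters).
#' @param eta_plus step growth factor, `> 1`.
#' @param eta_minus step shrink factor, in `(0, 1)`.
#' @param delta0 initial step size.
#' @param delta_min,delta_max bounds every step size is clipped to.
#' @return object of class `rprop_state`.
#' @export
irprop_state <- function(theta, eta_plus = 1.2, eta_minus = 0.5,
                         delta0 = 0.0125, delta_min = 1e-6, delta_max = 1.0) {
  if (!(eta_minus > 0 && eta_minus < 1 && eta_plus > 1)) {
    stopf("need 0 < eta_minus < 1 < eta_plus")
  }
  if (!(delta_min <= delta0 && delta0 <= delta_max)) {
    stopf("need delta_min <= delta0 <= delta_max")
  }
  zero_like <- function(x) {x[] <- 0; x}
  structure(list(
    step_sizes = lapply(theta, function(x) {x[] <- delta0; x}),
    prev_grad = lapply(theta, zero_like),
    prev_update = lapply(theta, zero_like),
    prev_loss = Inf,
    hyper = list(eta_plus = eta_plus, eta_minus = eta_minus, delta0 = delta0,
                 delta_min = delta_min, delta_max = delta_max)
  ), class = "rprop_state")
}

#' One iRprop+ update
#'
#' Elementwise, with `s = prev_grad * grad`:
#' * `s > 0`: grow the step size by `eta_plus` (capped at `delta_max`) and
#'   move against the gradient sign;
#' * `s < 0`: shrink the step size by `eta_minus` (floored at `delta_min`),
#'   revert the previous update if the loss increased, and zero the stored
#'   gradient so the next step is treated as a fresh start (no move now);
#' * `s = 0`: move against the gradient sign at the current step size.
#'
#' `loss` must be the objective value at `theta` (before the update), which
#' is what the backtracking test compares against the previous epoch's loss.
#'
#' @param theta named list of numeric arrays.
#' @param grad matching list of gradient arrays.
#' @param loss scalar loss at `theta`.
#' @param state an [irprop_state()].
#' @return list with updated `theta` and `state`.
#' @export
irprop_plus_step <- function(theta, grad, loss, state) {
  if (!is_scalar_number(loss)) stopf("`loss` must be a finite scalar")
  if (any(!vapply(grad, function(g) all(is.finite(g)), logical(1L)))) {
    stopf("non-finite gradient encountered; training aborted")
  }
  h <- state$hyper
  worse <- loss > state$prev_loss
  for (j in seq_along(theta)) {
    g <- grad[[j]]
    pg <- state$prev_grad[[j]]
    d <- state$step_sizes[[j]]
    pu <- state$prev_update[[j]]
    s <- pg * g
    pos <- s > 0
    neg <- s < 0
    d[pos] <- pmin(d[pos] * h$eta_plus, h$delta_max)
    d[neg] <- pmax(d[neg] * h$eta_minus, h$delta_min)
    upd <- g
    upd[] <- 0
    move <- !neg
    upd[move] <- -sign(g[move]) * d[move]
    if (worse) upd[neg] <- -pu[neg]
    theta[[j]] <- theta[[j]] + upd
    g[neg] <- 0
    state$prev_grad[[j]] <- g
    upd[neg] <- 0
    state$prev_update[[j]] <- upd
    state$step_sizes[[j]] <- d
  }
  state$prev_loss <- loss
  list(theta = theta, state = state)
}

# Pack / unpack network parameters (+ optional untied linear stack) and the
# latent input into the flat list the optimizer works on.
pack_model <- function(params, Z, params_linear = NULL, train_bias = TRUE) {
  theta <- list()
  for (l in seq_along(params$weights)) theta[[paste0("W", l)]] <- params$weights[[l]]
  if (train_bias) for (l in seq_along(params$biases)) theta[[paste0("b", l)]] <- params$biases[[l]]
  if (!is.null(params_linear)) {
    for (l in seq_along(params_linear$weights)) theta[[paste0("Wl", l)]] <- params_linear$weights[[l]]
    if (train_bias) for (l in seq_along(params_linear$biases)) theta[[paste0("bl", l)]] <- params_linear$biases[[l]]
  }
  theta$Z <- as_latent(Z)$Z
  theta
}

unpack_model <- function(theta, params, params_linear = NULL) {
  for (l in seq_along(params$weights)) {
    params$weights[[l]] <- theta[[paste0("W", l)]]
    bl <- theta[[paste0("b", l)]]
    if (!is.null(bl)) params$biases[[l]] <- bl
  }
  if (!is.null(params_linear)) {
    for (l in seq_along(params_linear$weights)) {
      params_linear$weights[[l]] <- theta[[paste0("Wl", l)]]
      bl <- theta[[paste0("bl", l)]]
      if (!is.null(bl)) params_linear$biases[[l]] <- bl
    }
  }
  list(params = params, params_linear = params_linear, Z = theta$Z)
}

pack_grad <- function(gr, train_bias = TRUE, untied = FALSE) {
  g <- list()
  for (l in seq_along(gr$weights)) g[[paste0("W", l)]] <- gr$weights[[l]]
  if (train_bias) for (l in seq_along(gr$biases)) g[[paste0("b", l)]] <- gr$biases[[l]]
  if (untied) {
    for (l in seq_along(gr$weights_linear)) g[[paste0("Wl", l)]] <- gr$weights_linear[[l]]
    if (train_bias) for (l in seq_along(gr$biases_linear)) g[[paste0("bl", l)]] <- gr$biases_linear[[l]]
  }
  g$Z <- gr$Z
  g
}

#' Train one dual-branch network with iRprop+
#'
#' Initializes the weight stack (Glorot Gaussian weights, zero biases) and
#' the latent input (zeros), then iterates full-batch loss + gradient +
#' [irprop_plus_step()] until `max_epochs` is reached or the relative loss
#' change stays below `rel_tol` for `patience` consecutive epochs. Fully
#' deterministic given `seed`.
#'
#' @param rm a [response_matrix()] (rows = network output units, columns =
#'   latent-input columns).
#' @param r latent rank, `< min(dim(rm))` recommended.
#' @param hidden_sizes integer vector of hidden widths (possibly empty).
#' @param alpha nonlinear-branch blend weight in `[0, 1]`.
#' @param lam regularization weight `>= 0`.
#' @param activation nonlinearity name; see [network_params()].
#' @param opts list of options: `max_epochs` (default 2000), `rel_tol`
#'   (1e-6), `patience` (5), `train_bias` (TRUE; FALSE freezes biases at 0),
#'   `tied_branches` (TRUE), `linear_output` (FALSE), and the iRprop+
#'   constants `eta_plus`, `eta_minus`, `delta0`, `delta_min`, `delta_max`.
#' @param seed integer seed for the weight initialization.
#' @return list with `params` (and `params_linear` if untied), `Z`
#'   (`latent_input`), `loss_history`, `epochs`, `status` (`"converged"`,
#'   `"max_epochs"` or `"diverged"`).
#' @export
train_network <- function(rm, r, hidden_sizes, alpha, lam,
                          activation = "tanh", opts = list(), seed = 1L) {
  assert_response_matrix(rm)
  o <- utils::modifyList(list(
    max_epochs = 2000L, rel_tol = 1e-6, patience = 5L,
    train_bias = TRUE, tied_branches = TRUE, linear_output = FALSE,
    eta_plus = 1.2, eta_minus = 0.5, delta0 = 0.0125,
    delta_min = 1e-6, delta_max = 1.0, verbose = FALSE
  ), opts)
  m <- nrow(rm$values)
  n <- ncol(rm$values)
  params <- network_params(r, hidden_sizes, m, activation = activation,
                           seed = seed, linear_output = o$linear_output)
  params_linear <- if (o$tied_branches) NULL else {
    network_params(r, hidden_sizes, m, activation = activation,
                   seed = seed + 1000L, linear_output = o$linear_output)
  }
  Z <- latent_input(r, n, init = "zero")
  theta <- pack_model(params, Z, params_linear, o$train_bias)
  state <- irprop_state(theta, o$eta_plus, o$eta_minus, o$delta0,
                        o$delta_min, o$delta_max)
  loss_history <- numeric(0)
  status <- "max_epochs"
  still <- 0L
  prev_loss <- NA_real_
  theta_good <- theta
  for (epoch in seq_len(o$max_epochs)) {
    mdl <- unpack_model(theta, params, params_linear)
    loss <- masked_loss(mdl$params, mdl$Z, rm, alpha, lam, mdl$params_linear)
    if (!is.finite(loss)) {
      status <- "diverged"
      warning("non-finite loss; returning the last finite model", call. = FALSE)
      theta <- theta_good
      break
    }
    theta_good <- theta
    loss_history <- c(loss_history, loss)
    if (o$verbose && epoch %% 50L == 0L) {
      message(sprintf("epoch %d: loss %.6g", epoch, loss))
    }
    if (!is.na(prev_loss)) {
      rel <- abs(loss - prev_loss) / max(abs(prev_loss), .Machine$double.eps)
      still <- if (rel < o$rel_tol) still + 1L else 0L
      if (still >= o$patience) {
        status <- "converged"
        break
      }
    }
    prev_loss <- loss
    gr <- network_gradients(mdl$params, mdl$Z, rm, alpha, lam, mdl$params_linear)
    step <- irprop_plus_step(theta, pack_grad(gr, o$train_bias, !is.null(params_linear)),
                             loss, state)
    theta <- step$theta
    state <- step$state
  }
  mdl <- unpack_model(theta, params, params_linear)
  list(params = mdl$params, params_linear = mdl$params_linear,
       Z = structure(list(Z = mdl$Z, r = as.integer(r)), class = "latent_input"),
       loss_history = loss_history, epochs = length(loss_history),
       status = status)
}
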