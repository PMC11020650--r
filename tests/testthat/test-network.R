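test_that("nonlinear forward matches hand evaluation on degenerate layers", {
  # all-zero single layer under tanh maps everything to zero
  p <- network_params(2, integer(0), 2, seed = 1)
  p$weights[[1]][] <- 0
  expect_equal(forward_nonlinear(p, matrix(c(0.3, -0.7), 2, 1)), matrix(0, 2, 1))
  # identity weights: tanh applied entrywise
  p$weights[[1]] <- diag(2)
  Z <- matrix(c(0.5, -0.5), 2, 1)
  expect_equal(forward_nonlinear(p, Z), tanh(Z))
})

test_that("both forward passes match column-by-column loop oracles", {
  for (s in 1:5) {
    p <- make_random_params(3, c(5, 4), 6, seed = s)
    Z <- dbdnmf:::with_seed(s + 50, matrix(rnorm(3 * 7), 3, 7))
    expect_lt(max(abs(forward_nonlinear(p, Z) - loop_forward_nonlinear(p, Z))), 1e-12)
    expect_lt(max(abs(forward_linear(p, Z) - loop_forward_linear(p, Z))), 1e-12)
  }
})

test_that("the implied factor matrix is the ordered weight product", {
  p1 <- make_random_params(3, integer(0), 4, seed = 2)
  expect_equal(implied_factor_matrix(p1), p1$weights[[1]])
  p2 <- make_random_params(3, c(3), 3, seed = 3)
  p2$weights[[2]] <- 2 * diag(3)
  expect_equal(implied_factor_matrix(p2), 2 * p2$weights[[1]])
  # zero biases: the linear branch IS the factor matrix times the input
  p3 <- network_params(2, c(4, 3), 5, seed = 4)
  Z <- dbdnmf:::with_seed(60, matrix(rnorm(2 * 6), 2, 6))
  expect_equal(forward_linear(p3, Z), implied_factor_matrix(p3) %*% Z)
})

test_that("predict_blend interpolates the two branches and validates alpha", {
  p <- make_random_params(2, c(3), 4, seed = 5)
  Z <- dbdnmf:::with_seed(61, matrix(rnorm(2 * 5), 2, 5))
  expect_equal(predict_blend(p, Z, 0), forward_linear(p, Z))
  expect_equal(predict_blend(p, Z, 1), forward_nonlinear(p, Z))
  expect_equal(predict_blend(p, Z, 0.5),
               (forward_nonlinear(p, Z) + forward_linear(p, Z)) / 2)
  expect_error(predict_blend(p, Z, 1.2), "alpha")
})

test_that("with identity activation the two branches coincide", {
  p <- make_random_params(2, c(3), 4, activation = "identity", seed = 6)
  Z <- dbdnmf:::with_seed(62, matrix(rnorm(2 * 5), 2, 5))
  expect_equal(forward_nonlinear(p, Z), forward_linear(p, Z))
})

test_that("mutating a shared weight changes both branches", {
  p <- make_random_params(2, c(3), 4, seed = 7)
  Z <- dbdnmf:::with_seed(63, matrix(rnorm(2 * 5), 2, 5))
  f0 <- forward_nonlinear(p, Z)
  g0 <- forward_linear(p, Z)
  p$weights[[1]][1, 1] <- p$weights[[1]][1, 1] + 0.5
  expect_false(isTRUE(all.equal(forward_nonlinear(p, Z), f0)))
  expect_false(isTRUE(all.equal(forward_linear(p, Z), g0)))
})

test_that("masked loss matches its definition and the scalar-loop oracle", {
  # perfect reconstruction with no penalty costs nothing
  p <- network_params(1, integer(0), 1, seed = 8)
  p$weights[[1]] <- matrix(1)
  rm1 <- response_matrix(matrix(0.4))
  expect_equal(masked_loss(p, matrix(atanh(0.4), 1, 1), rm1, 1, 0), 0)
  # single observed entry with residual 2 and eta = 1: loss = (1/2) * 4 = 2
  p0 <- network_params(1, integer(0), 1, seed = 9)
  p0$weights[[1]][] <- 0
  expect_equal(masked_loss(p0, matrix(0, 1, 1), response_matrix(matrix(2)), 0.5, 0), 2)
  # random instances against the brute-force oracle
  for (s in 1:5) {
    p <- make_random_params(2, c(3), 3, seed = s + 10)
    Z <- dbdnmf:::with_seed(s + 70, matrix(rnorm(2 * 4), 2, 4))
    rm <- make_random_rm(3, 4, n_missing = 2, seed = s + 20)
    expect_lt(abs(masked_loss(p, Z, rm, 0.35, 0.1) -
                  loop_masked_loss(p, Z, rm, 0.35, 0.1)), 1e-12)
  }
})

test_that("masked loss ignores values stored at unobserved entries", {
  p <- make_random_params(2, c(3), 3, seed = 30)
  Z <- dbdnmf:::with_seed(71, matrix(rnorm(2 * 4), 2, 4))
  rm <- make_random_rm(3, 4, n_missing = 3, seed = 31)
  l1 <- masked_loss(p, Z, rm, 0.5, 0.01)
  rm2 <- rm
  rm2$values[rm2$mask == 0] <- 1e6
  expect_identical(masked_loss(p, Z, rm2, 0.5, 0.01), l1)
})

test_that("backprop gradients match central finite differences", {
  for (s in 1:6) {
    cfg <- dbdnmf:::with_seed(s + 200, list(
      m = sample(2:5, 1), n = sample(2:6, 1), r = sample(1:3, 1),
      L = sample(0:2, 1), alpha = runif(1), lam = runif(1, 0, 0.2)))
    hidden <- if (cfg$L > 0) rep(3, cfg$L) else integer(0)
    p <- make_random_params(cfg$r, hidden, cfg$m, seed = s + 300)
    Z <- dbdnmf:::with_seed(s + 400, matrix(rnorm(cfg$r * cfg$n), cfg$r, cfg$n))
    rm <- make_random_rm(cfg$m, cfg$n, n_missing = 1, seed = s + 500)
    gr <- network_gradients(p, Z, rm, cfg$alpha, cfg$lam)
    fd <- fd_network_gradients(p, Z, rm, cfg$alpha, cfg$lam)
    expect_lt(grad_max_rel_err(gr, fd), 1e-5)
  }
})

test_that("gradients vanish at a zero-residual point and reduce to the penalty", {
  # rank-1 exact fit, alpha = 0, lam = 0: stationary point of the data term
  W <- matrix(c(1, 2), 2, 1)
  Z <- matrix(c(3, 4, 5), 1, 3)
  rm <- response_matrix(W %*% Z)
  p <- network_params(1, integer(0), 2, seed = 40)
  p$weights[[1]] <- W
  gr <- network_gradients(p, Z, rm, 0, 0)
  expect_lt(max(abs(gr$weights[[1]])), 1e-14)
  expect_lt(max(abs(gr$Z)), 1e-14)
  # with lam > 0 the only addition is the quadratic penalty gradient
  lam <- 0.3
  gr2 <- network_gradients(p, Z, rm, 0, lam)
  expect_equal(unname(gr2$weights[[1]]), lam * W)
  expect_equal(unname(gr2$Z), lam * Z / ncol(Z))
})

test_that("the single-layer linear case reduces to the classical MF gradient", {
  dbdnmf:::with_seed(90, {
    m <- 4; n <- 5; r <- 2; lam <- 0.05
    W <- matrix(rnorm(m * r), m, r)
    Z <- matrix(rnorm(r * n), r, n)
    vals <- matrix(rnorm(m * n), m, n); vals[sample(m * n, 4)] <- NA
    rm <- response_matrix(vals)
    p <- network_params(r, integer(0), m, seed = 91)
    p$weights[[1]] <- W
    gr <- network_gradients(p, Z, rm, 0, lam)
    eta <- sum(rm$mask)
    E <- W %*% Z - rm$values
    E[rm$mask == 0] <- 0
    expect_equal(gr$weights[[1]], (E %*% t(Z)) / eta + lam * W)
    expect_equal(gr$Z, (t(W) %*% E) / eta + lam * Z / n)
  })
})

test_that("untied branches carry separate weight stacks and exact gradients", {
  p_nl <- make_random_params(2, c(3), 3, seed = 50)
  p_li <- make_random_params(2, c(3), 3, seed = 51)
  Z <- dbdnmf:::with_seed(52, matrix(rnorm(2 * 4), 2, 4))
  rm <- make_random_rm(3, 4, n_missing = 2, seed = 53)
  alpha <- 0.4; lam <- 0.05
  l <- masked_loss(p_nl, Z, rm, alpha, lam, params_linear = p_li)
  gr <- network_gradients(p_nl, Z, rm, alpha, lam, params_linear = p_li)
  # finite differences on one weight of each stack
  h <- 1e-6
  bump <- function(p, dl) {q <- p; q$weights[[1]][1, 1] <- q$weights[[1]][1, 1] + dl; q}
  fd_nl <- (masked_loss(bump(p_nl, h), Z, rm, alpha, lam, params_linear = p_li) -
            masked_loss(bump(p_nl, -h), Z, rm, alpha, lam, params_linear = p_li)) / (2 * h)
  fd_li <- (masked_loss(p_nl, Z, rm, alpha, lam, params_linear = bump(p_li, h)) -
            masked_loss(p_nl, Z, rm, alpha, lam, params_linear = bump(p_li, -h))) / (2 * h)
  expect_lt(abs(gr$weights[[1]][1, 1] - fd_nl), 1e-6)
  expect_lt(abs(gr$weights_linear[[1]][1, 1] - fd_li), 1e-6)
  expect_gt(abs(l), 0)
})

test_that("dimension mismatches are rejected with layer context", {
  p <- make_random_params(3, c(4), 5, seed = 60)
  expect_error(forward_nonlinear(p, matrix(0, 2, 3)), "layer 1 expects 3")
  rm <- make_random_rm(5, 4, seed = 61)
  expect_error(masked_loss(p, matrix(0, 3, 7), rm, 0.5, 0), "columns")
  expect_error(masked_loss(p, matrix(0, 3, 4), rm, 0.5, -1), "lam")
})
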