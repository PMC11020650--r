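# Small architectures and capped epochs keep these pipeline tests fast; the
# full-size benchmark lives in the acceptance suite.
fast_cfg <- function(...) {
  dbdnmf_config(rank = 2, hidden_sizes = c(6), lam = 0.001,
                opts = list(max_epochs = 200), seed = 1, ...)
}

test_that("config validation and side selection work", {
  expect_error(dbdnmf_config(alpha = 1.5), "alpha")
  expect_error(dbdnmf_config(lam = -1), "lam")
  expect_error(dbdnmf_config(rank = 0), "rank")
  rm <- make_random_rm(8, 6, n_missing = 5, seed = 1)
  fit_col <- dbdnmf_fit(rm, fast_cfg(side = "column_net"))
  expect_null(fit_col$row_model)
  expect_false(is.null(fit_col$column_model))
  fit_row <- dbdnmf_fit(rm, fast_cfg(side = "row_net"))
  expect_null(fit_row$column_model)
  expect_error(dbdnmf_fit(rm, dbdnmf_config(rank = 6)), "rank")
})

test_that("completion preserves observed entries and is the identity on full matrices", {
  rm <- make_random_rm(8, 6, n_missing = 7, seed = 2)
  model <- dbdnmf_fit(rm, fast_cfg())
  comp <- dbdnmf_complete(model, rm)
  obs <- rm$mask == 1
  expect_identical(comp$values[obs], rm$values[obs])
  expect_true(all(comp$mask == 1))
  full <- make_random_rm(7, 5, seed = 3)
  model_f <- dbdnmf_fit(full, fast_cfg())
  expect_identical(dbdnmf_complete(model_f, full)$values, full$values)
})

test_that("two fits with the same data and config are identical", {
  rm <- make_random_rm(8, 6, n_missing = 5, seed = 4)
  cfg <- fast_cfg()
  m1 <- dbdnmf_fit(rm, cfg)
  m2 <- dbdnmf_fit(rm, cfg)
  expect_identical(dbdnmf_complete(m1, rm)$values, dbdnmf_complete(m2, rm)$values)
})

test_that("both_mean completions average the two single-side completions", {
  rm <- make_random_rm(8, 6, n_missing = 6, seed = 5)
  comp_both <- dbdnmf_complete(dbdnmf_fit(rm, fast_cfg(side = "both_mean")), rm)
  comp_col <- dbdnmf_complete(dbdnmf_fit(rm, fast_cfg(side = "column_net")), rm)
  comp_row <- dbdnmf_complete(dbdnmf_fit(rm, fast_cfg(side = "row_net")), rm)
  fill <- rm$mask == 0
  expect_equal(comp_both$values[fill],
               (comp_col$values[fill] + comp_row$values[fill]) / 2)
})

test_that("identifier mismatches are rejected at completion", {
  rm <- make_random_rm(6, 5, n_missing = 3, seed = 6)
  model <- dbdnmf_fit(rm, fast_cfg())
  other <- response_matrix(rm$values, drug_ids = paste0("x", 1:6))
  expect_error(dbdnmf_complete(model, other), "identifiers")
})

test_that("the pipeline degenerates to rank-1 bilinear factorization", {
  u <- dbdnmf:::with_seed(7, rnorm(10))
  v <- dbdnmf:::with_seed(8, rnorm(8))
  rm <- response_matrix(outer(u, v))
  cfg <- dbdnmf_config(rank = 1, hidden_sizes = integer(0), alpha = 0, lam = 0,
                       use_ger = FALSE, side = "column_net",
                       opts = list(max_epochs = 500, train_bias = FALSE), seed = 9)
  model <- dbdnmf_fit(rm, cfg)
  pred <- forward_linear(model$column_model$params, model$column_model$Z)
  expect_lt(sqrt(mean((pred - rm$values)^2)), 1e-3)
})

test_that("a pure additive-effects matrix is completed by the effects alone", {
  ge <- structure(list(global_mean = 2,
                       drug_effects = dbdnmf:::with_seed(10, rnorm(9, sd = 1)),
                       cell_effects = dbdnmf:::with_seed(11, rnorm(7, sd = 1))),
                  class = "global_effects")
  vals <- dbdnmf:::effects_matrix(ge, 9, 7)
  hide <- dbdnmf:::with_seed(12, sample(63, 15))
  masked <- vals
  masked[hide] <- NA
  rm <- response_matrix(masked)
  model <- dbdnmf_fit(rm, fast_cfg(use_ger = TRUE))
  comp <- dbdnmf_complete(model, rm)
  expect_lt(max(abs(comp$values[hide] - vals[hide])), 0.05)
})

test_that("the model beats mean imputation on blended low-rank data", {
  st <- generate_synthetic(synthetic_spec(m = 30, n = 20, r = 3, seed = 21))
  rm <- st$observed
  model <- dbdnmf_fit(rm, dbdnmf_config(rank = 3, lam = 0.001,
                                        opts = list(max_epochs = 800), seed = 2))
  comp <- dbdnmf_complete(model, rm)
  miss <- rm$mask == 0
  truth <- st$full_matrix[miss] # noise-free ground truth at unobserved cells
  model_rmse <- sqrt(mean((comp$values[miss] - truth)^2))
  row_means <- rowMeans(rm$values, na.rm = TRUE)
  baseline_rmse <- sqrt(mean((matrix(row_means, 30, 20)[miss] - truth)^2))
  expect_lt(model_rmse, 0.5 * baseline_rmse)
})

test_that("leave-one-out CV scores every observed entry exactly once", {
  rm <- make_random_rm(4, 4, seed = 22)
  cfg <- dbdnmf_config(rank = 2, hidden_sizes = c(4), lam = 0.001,
                       opts = list(max_epochs = 50), seed = 3)
  cv <- dbdnmf_cv(rm, cfg, k = 16, seed = 5)
  expect_equal(nrow(cv$fold_metrics), 16)
  expect_equal(sum(cv$fold_metrics$n_test), 16)
  expect_false(any(is.na(cv$predictions)))
})

test_that("CV predictions cover originally missing cells without scoring them", {
  rm <- make_random_rm(8, 6, n_missing = 8, seed = 23)
  cv <- dbdnmf_cv(rm, fast_cfg(), k = 3, seed = 7)
  expect_false(any(is.na(cv$predictions)))
  expect_equal(sum(cv$fold_metrics$n_test), sum(rm$mask))
  # metrics are computed on the observed mask only
  expect_equal(sum(cv$overall$per_drug$n_test), sum(rm$mask))
})

test_that("cold-start evaluation yields one row per unit with observations", {
  rm <- make_random_rm(5, 6, seed = 24)
  cfg <- fast_cfg()
  res <- cold_start_evaluate(rm, cfg, axis = "drug")
  expect_equal(nrow(res$per_unit), 5)
  expect_equal(res$summary$n_units, 5)
  res_c <- cold_start_evaluate(rm, cfg, axis = "cellline")
  expect_equal(nrow(res_c$per_unit), 6)
})

test_that("a constant matrix is predicted near its constant in cold-start", {
  rm <- response_matrix(matrix(3, 6, 5))
  cfg <- dbdnmf_config(rank = 2, hidden_sizes = c(4), lam = 0.001,
                       opts = list(max_epochs = 300), seed = 11)
  res <- cold_start_evaluate(rm, cfg, axis = "drug")
  expect_lt(max(res$per_unit$rmse), 0.05)
})

test_that("alpha sweep tabulates the requested grid", {
  rm <- make_random_rm(8, 6, n_missing = 5, seed = 25)
  cfg <- dbdnmf_config(rank = 2, hidden_sizes = c(4), lam = 0.001,
                       opts = list(max_epochs = 60), seed = 4)
  tab <- alpha_sweep(rm, cfg, alphas = c(0.2, 0.8), sides = "column_net",
                     k = 2, seed = 6)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$alpha, c(0.2, 0.8))
  expect_true(all(c("ave_pcc", "ave_rmse", "ave_pcc_sr", "ave_rmse_sr") %in% names(tab)))
})

test_that("models survive a save/load round trip", {
  rm <- make_random_rm(6, 5, n_missing = 3, seed = 26)
  model <- dbdnmf_fit(rm, fast_cfg())
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(dbdnmf_complete(back, rm)$values, dbdnmf_complete(model, rm)$values)
})
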