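test_that("the path is all-zero at lambda_max and matches soft-thresholding on orthonormal designs", {
  cfg <- selection_config(standardize = FALSE, thresh = 1e-12)
  for (seed in 1:5) {
    X <- orthonormal_design(40, 8, seed = seed)
    set.seed(seed + 500)
    beta <- rnorm(8, 0, 0.5)
    y <- drop(X %*% beta) + rnorm(40, 0, 0.2)
    fit <- fit_elastic_net_path(X, y, cfg)
    expect_equal(unname(fit$path[, 1L]), rep(0, 8))  # definition of lambda_max
    b_ols <- drop(crossprod(X, y)) / nrow(X)
    for (li in c(1L, 25L, 50L, 100L)) {
      lam <- fit$lambda_grid[li]
      oracle <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
      expect_equal(unname(fit$path[, li]), unname(oracle), tolerance = 1e-6)
    }
  }
})

test_that("ridge assigns equal coefficients to duplicated columns", {
  set.seed(9)
  x1 <- rnorm(50)
  X <- cbind(a = x1, b = x1 + rnorm(50, 0, 1e-10), c = rnorm(50))
  y <- x1 + rnorm(50, 0, 0.1)
  fit <- fit_elastic_net_path(X, y, selection_config(alpha = 0,
                                                     standardize = FALSE,
                                                     thresh = 1e-12))
  i <- length(fit$lambda_grid) %/% 2L
  expect_equal(fit$path["a", i], fit$path["b", i], tolerance = 1e-4)
})

test_that("the path approaches OLS at the smallest penalty when n >> P", {
  set.seed(10)
  X <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("V", 1:4)))
  beta <- c(1, -2, 0.5, 0)
  y <- drop(X %*% beta) + rnorm(200, 0, 0.3)
  fit <- fit_elastic_net_path(X, y, selection_config(standardize = FALSE,
                                                     thresh = 1e-12))
  ols <- coef(lm(y ~ X))[-1]
  last <- fit$path[, ncol(fit$path)]
  expect_equal(unname(last), unname(ols), tolerance = 1e-3)
})

test_that("leave-one-out CV has n folds, matches the intercept-only closed form at lambda_max, and is deterministic", {
  set.seed(11)
  X <- orthonormal_design(25, 5, seed = 11)
  y <- rnorm(25)
  cfg <- selection_config(standardize = FALSE)
  fit <- loo_cv(fit_elastic_net_path(X, y, cfg), cfg)
  n <- length(y)
  # at the grid top the model is intercept-only up to the fact that a
  # leave-one-out refit can have a slightly larger entry penalty than the
  # full-data lambda_max; the CV error approaches the closed-form LOO error
  # of the intercept-only model
  loo_mean <- vapply(seq_len(n), function(i) mean(y[-i]), 0)
  expect_equal(fit$cv_mse[1L], mean((y - loo_mean)^2), tolerance = 0.05)
  expect_equal(fit$cv_se[1L], sd((y - loo_mean)^2) / sqrt(n),
               tolerance = 0.05)
  expect_length(fit$cv_mse, length(fit$lambda_grid))
  expect_true(fit$lambda_min %in% fit$lambda_grid)
  # no randomness anywhere in LOO
  fit2 <- loo_cv(fit_elastic_net_path(X, y, cfg), cfg)
  expect_identical(fit$cv_mse, fit2$cv_mse)
})

test_that("the one-SE choice is never below the CV minimizer", {
  for (seed in 1:8) {
    set.seed(seed + 40)
    X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("V", 1:6)))
    y <- drop(X %*% c(0.6, -0.6, rep(0, 4))) + rnorm(30, 0, 0.4)
    fit <- select_virtual_genes(X, y)
    expect_gte(fit$lambda_chosen, fit$lambda_min)
    fit_min <- select_lambda(fit, selection_config(rule = "min"))
    expect_equal(fit_min$lambda_chosen, fit_min$lambda_min)
    # nonzero coefficients and the selected set coincide
    expect_setequal(names(fit$coefficients[fit$coefficients != 0]),
                    fit$selected)
  }
})

test_that("path ranking follows entry order and equals correlation ranking on orthonormal designs", {
  set.seed(12)
  X <- orthonormal_design(60, 10, seed = 12)
  beta <- c(1.2, -0.8, 0.5, rep(0, 7))
  y <- drop(X %*% beta) + rnorm(60, 0, 0.1)
  fit <- select_virtual_genes(X, y, selection_config(standardize = FALSE))
  rk <- fit$ranking
  # the largest |OLS| coefficient survives longest on the path: rank 1
  b_ols <- abs(drop(crossprod(X, y)) / nrow(X))
  expect_identical(rk[1L], names(sort(b_ols, decreasing = TRUE))[1L])
  # orthonormal design: path order equals |correlation| order
  expect_identical(rk, rank_by_correlation(X, y)$ranking)
})

test_that("an all-zero path falls back to deterministic column-order ranking", {
  X <- orthonormal_design(20, 4, seed = 13)
  fit <- fit_elastic_net_path(X, rep(c(1, -1), 10),
                              selection_config(n_lambda = 5,
                                               lambda_min_ratio = 0.9))
  fit$path[] <- 0
  expect_identical(rank_features_by_path(fit), colnames(X))
})

test_that("selection rejects unusable inputs", {
  X <- orthonormal_design(20, 4, seed = 14)
  expect_error(fit_elastic_net_path(X, c(rep(1, 19), NA)),
               class = "modstick_validation_error")
  X2 <- cbind(X, Z = rep(1, 20))
  expect_warning(fit <- fit_elastic_net_path(X2, rnorm(20)),
                 class = "modstick_degenerate")
  expect_false("Z" %in% fit$feature_names)
})
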