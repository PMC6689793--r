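test_that("simulated responses are reproducible with the stated noise law", {
  X <- orthonormal_design(10, 3, seed = 30)
  beta <- c(0.5, 0, -0.5)
  y1 <- simulate_response(X, beta, sigma = 0.2, seed = 7)
  y2 <- simulate_response(X, beta, sigma = 0.2, seed = 7)
  expect_identical(y1, y2)
  expect_equal(unname(simulate_response(X, rep(0, 3), sigma = 1e-12, seed = 1)),
               rep(0, 10), tolerance = 1e-9)
  # residual variance over many draws approaches sigma^2 (within 5%)
  set.seed(8)
  resid <- as.numeric(replicate(1000, simulate_response(X, beta, 0.3) -
                                  drop(X %*% beta)))
  expect_equal(var(resid), 0.09, tolerance = 0.05)
  expect_error(simulate_response(X, c(1, 2), 0.1),
               class = "modstick_validation_error")
})

test_that("average precision matches its defining formula", {
  # perfect ranking
  expect_equal(pr_auc(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE)), 1)
  # a single positive ranked last among N features scores 1/N
  N <- 7
  expect_equal(pr_auc(seq(N, 1), c(rep(FALSE, N - 1), TRUE)), 1 / N)
  # random instances vs the brute-force transcription
  for (seed in 1:20) {
    set.seed(seed)
    sc <- rnorm(30); tr <- runif(30) < 0.3
    if (!any(tr)) tr[1] <- TRUE
    expect_equal(pr_auc(sc, tr), ap_brute(sc, tr), tolerance = 1e-12)
  }
  expect_error(pr_auc(1:3, rep(FALSE, 3)), class = "modstick_validation_error")
})

test_that("random rankings score at the exact average-precision baseline", {
  # under a uniformly random ranking, E[# positives at depth i | positive
  # at i] = 1 + (i-1)(P-1)/(N-1), so the exact expected average precision
  # is (1/N) * sum_i [1 + (i-1)(P-1)/(N-1)] / i -- slightly above the
  # prevalence P/N at these sizes
  N <- 51; P <- 8
  i <- seq_len(N)
  exact <- mean((1 + (i - 1) * (P - 1) / (N - 1)) / i)
  set.seed(31)
  truth <- c(rep(TRUE, P), rep(FALSE, N - P))
  aucs <- replicate(10000, pr_auc(rnorm(N), truth))
  expect_equal(mean(aucs), exact, tolerance = 0.01)
  expect_gt(exact, P / N)
})

test_that("correlation ranking matches a brute-force computation", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(NULL, paste0("V", 1:10)))
    y <- rnorm(20)
    r <- rank_by_correlation(X, y)
    brute <- sapply(seq_len(10), function(j) abs(cor(X[, j], y)))
    expect_equal(unname(r$scores), brute, tolerance = 1e-12)
    expect_identical(r$ranking, colnames(X)[order(-brute)])
  }
  # y equal to one column puts it first with |cor| = 1
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  r <- rank_by_correlation(X, X[, "b"])
  expect_identical(r$ranking[1L], "b")
  expect_equal(unname(r$scores["b"]), 1, tolerance = 1e-12)
})

test_that("simulation runs are seed-deterministic with per-replicate records", {
  X <- generate_design_matrix(40, 12, 0, seed = 32)
  spec <- simulation_spec(X, effect_sizes = c(0.1, 0.5), n_rep = 5L,
                          seed = 99L)
  r1 <- run_simulation_II(spec)
  r2 <- run_simulation_II(spec)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 2L * 5L * 2L)  # settings x replicates x methods
  expect_true(all(r1$pr_auc >= 0 & r1$pr_auc <= 1))

  spec1 <- simulation_spec(X, true_support = c(1L, 4L, 7L),
                           base_coefficients = c(0.4, -0.4, 0.4),
                           factors = c(0.5, 1), n_rep = 4L, seed = 7L)
  s1 <- run_simulation_I(spec1)
  expect_identical(s1, run_simulation_I(spec1))
  expect_identical(nrow(s1), 2L * 4L * 2L)
})

test_that("method comparison reproduces exact signed-rank p-values", {
  # identical vectors -> p = 1 with warning
  res <- data.frame(setting = 1, replicate = rep(1:4, 2),
                    method = rep(c("lasso_path", "correlation"), each = 4),
                    pr_auc = rep(c(.2, .3, .4, .5), 2))
  expect_warning(cmp <- compare_methods(res), class = "modstick_degenerate")
  expect_equal(cmp$p_value, 1)

  # a uniform +0.1 advantage across 100 pairs is extreme
  set.seed(33)
  base <- runif(100, 0.2, 0.6)
  res2 <- data.frame(setting = 1, replicate = rep(1:100, 2),
                     method = rep(c("lasso_path", "correlation"), each = 100),
                     pr_auc = c(base + 0.1, base))
  cmp2 <- compare_methods(res2)
  expect_lt(cmp2$p_value, 0.001)
  expect_identical(cmp2$label, "***")

  # exact-distribution oracle for n <= 10 untied pairs
  for (seed in 1:5) {
    set.seed(seed + 60)
    n <- sample(5:9, 1)
    a <- round(runif(n), 3); d <- round(runif(n, -0.4, 0.4), 3)
    d <- d + (d == 0) * 0.011 + seq_len(n) * 1e-4  # no zeros, no ties
    b <- a - d
    res3 <- data.frame(setting = 1, replicate = rep(seq_len(n), 2),
                       method = rep(c("lasso_path", "correlation"), each = n),
                       pr_auc = c(a, b))
    p_pkg <- compare_methods(res3)$p_value
    expect_equal(p_pkg, signed_rank_exact_p(d), tolerance = 1e-12)
  }
})
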