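test_that("gene contributions are squared loadings summing to one", {
  set.seed(20)
  pat <- rnorm(15)
  fc <- t(replicate(10, pat))  # identical genes -> contribution 1/10 each
  dimnames(fc) <- list(paste0("g", 1:10), paste0("A", 1:15))
  d <- decompose_module(fc, rownames(fc))
  ct <- gene_contributions(d, 1L)
  expect_equal(unname(ct$contributions), rep(0.1, 10), tolerance = 1e-9)
  expect_equal(sum(ct$contributions), 1, tolerance = 1e-9)
  expect_error(gene_contributions(d, 5L), class = "modstick_validation_error")

  # loadings (0.6, 0.8) -> contributions (0.36, 0.64)
  expect_equal(c(0.6, 0.8)^2, c(0.36, 0.64))

  set.seed(21)
  fc2 <- planted_fc(c(7), 20, within_noise = 0.5, seed = 21)
  d2 <- decompose_module(fc2, rownames(fc2))
  for (pc in seq_len(ncol(d2$loadings)))
    expect_equal(sum(gene_contributions(d2, pc)$contributions), 1,
                 tolerance = 1e-9)
})

test_that("broken-stick null matches closed-form quantities", {
  # K = 1: the whole stick
  expect_identical(broken_stick_null(1, seed = 1)$thresholds, 1)

  # K = 2: P(largest <= t) = 2t - 1 on [1/2, 1], so the 95% point is 0.975
  null2 <- broken_stick_null(2, n_draws = 10000, seed = 2)
  expect_equal(null2$thresholds[1L], 0.975, tolerance = 0.01)

  # K = 3: E[largest] = (1 + 1/2 + 1/3)/3 = 11/18
  set.seed(3)
  e <- matrix(rexp(10000 * 3), ncol = 3); e <- e / rowSums(e)
  expect_equal(mean(apply(e, 1, max)), 11 / 18, tolerance = 0.01)
})

test_that("null thresholds are monotone in rank and bit-reproducible", {
  for (K in c(2, 5, 20, 60)) {
    null <- broken_stick_null(K, n_draws = 4000, seed = K)
    expect_true(all(diff(null$thresholds) <= 0))
    expect_true(all(null$thresholds > 0 & null$thresholds <= 1))
    null_again <- broken_stick_null(K, n_draws = 4000, seed = K)
    expect_identical(null$thresholds, null_again$thresholds)
  }
})

test_that("the contribution test flags what the null says it should", {
  # uniform contributions (the null mean) are never unusual
  d_flat <- list(module_id = 1L, pc_index = 1L,
                 gene_ids = paste0("g", 1:10),
                 contributions = setNames(rep(0.1, 10), paste0("g", 1:10)))
  class(d_flat) <- "modstick_contributions"
  null10 <- broken_stick_null(10, n_draws = 10000, seed = 4)
  res <- test_genes(d_flat, null10)
  expect_identical(sum(res$table$significant), 0L)

  # one dominant gene at 0.9 clears the K = 10 largest-piece threshold
  ct <- d_flat
  ct$contributions <- setNames(c(0.9, rep(0.1 / 9, 9)), paste0("g", 1:10))
  res2 <- test_genes(ct, null10)
  expect_true(res2$table$significant[1L])
  expect_identical(res2$table$gene_id[1L], "g1")
  expect_lt(null10$thresholds[1L], 0.6)

  # contiguous rule yields a contiguous top set; significant implies
  # contribution above the matched threshold
  with(res2$table, {
    expect_true(all(diff(significant) <= 0))
    expect_true(all(contribution[significant] > threshold[significant]))
  })

  # K mismatch is an error
  expect_error(test_genes(ct, broken_stick_null(5, 100, seed = 1)),
               class = "modstick_validation_error")
})

test_that("contiguous rule stops at the first failing rank; all-ranks mode does not", {
  ct <- list(module_id = 1L, pc_index = 1L, gene_ids = paste0("g", 1:6),
             contributions = setNames(c(0.5, 0.05, 0.3, 0.1, 0.03, 0.02),
                                      paste0("g", 1:6)))
  class(ct) <- "modstick_contributions"
  null <- broken_stick_null(6, n_draws = 10000, seed = 5)
  cont <- test_genes(ct, null, rule = "contiguous")
  all_ranks <- test_genes(ct, null, rule = "all")
  # sorted contributions: .5, .3, .1, .05, .03, .02; rank 2 (0.3) is below
  # the second-piece threshold or not, but the contiguous set can never be
  # larger than the all-ranks set
  expect_true(all(cont$table$significant <= all_ranks$table$significant))
})

test_that("gene-PC correlations behave as reporting diagnostics", {
  set.seed(22)
  n <- 30
  p1 <- drop(scale(rnorm(n)))
  p2 <- drop(scale(residuals(lm(rnorm(n) ~ p1))))  # orthogonal to p1
  fc <- rbind(same = p1, anti = -p1, ortho = p2)
  colnames(fc) <- paste0("A", seq_len(n))
  r <- gene_pc_correlation(fc, rownames(fc), p1)
  expect_equal(unname(r), c(1, -1, 0), tolerance = 1e-12)
  fc_const <- rbind(fc, const = rep(1, n))
  expect_error(gene_pc_correlation(fc_const, rownames(fc_const), p1),
               "const", class = "modstick_validation_error")
})
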