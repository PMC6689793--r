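test_that("a rank-1 module loads entirely on its first component", {
  set.seed(3)
  pat <- rnorm(12)
  fc <- t(replicate(10, pat))  # 10 identical genes
  dimnames(fc) <- list(paste0("g", 1:10), paste0("A", 1:12))
  d <- decompose_module(fc, rownames(fc))
  expect_equal(ncol(d$scores), 1L)  # j collapses to the rank
  expect_equal(d$var_fraction[1L], 1, tolerance = 1e-9)
  expect_equal(unname(d$loadings[, 1L]), rep(1 / sqrt(10), 10),
               tolerance = 1e-9)
})

test_that("two orthogonal equal-variance patterns split variance 50/50", {
  set.seed(4)
  n <- 40
  p1 <- drop(scale(rnorm(n)))
  p2 <- drop(scale(residuals(lm(rnorm(n) ~ p1))))
  fc <- rbind(t(replicate(5, p1)), t(replicate(5, p2)))
  dimnames(fc) <- list(paste0("g", 1:10), paste0("A", 1:n))
  d <- decompose_module(fc, rownames(fc))
  expect_equal(d$var_fraction[1:2], c(0.5, 0.5), tolerance = 1e-9)
  # PC1/PC2 span the two patterns
  expect_equal(max(abs(cor(d$scores[, 1L], p1)), abs(cor(d$scores[, 1L], p2))),
               1, tolerance = 1e-9)
  expect_equal(max(abs(cor(d$scores[, 2L], p1)), abs(cor(d$scores[, 2L], p2))),
               1, tolerance = 1e-9)
})

test_that("full-rank PCA reconstructs the standardized matrix", {
  set.seed(5)
  fc <- matrix(rnorm(6 * 20), 6, 20,
               dimnames = list(paste0("g", 1:6), paste0("A", 1:20)))
  d <- decompose_module(fc, rownames(fc), n_pcs = 6L)
  xs <- scale(t(fc))
  recon <- d$scores %*% t(d$loadings)
  expect_equal(unname(recon), unname(xs[, ]), tolerance = 1e-9)
})

test_that("variance fractions equal correlation-matrix eigenvalues over trace", {
  for (seed in 1:5) {
    set.seed(seed)
    ng <- sample(3:20, 1)
    fc <- matrix(rnorm(ng * 15), ng, 15,
                 dimnames = list(paste0("g", seq_len(ng)), paste0("A", 1:15)))
    d <- decompose_module(fc, rownames(fc), n_pcs = 3L)
    ev <- eigen(cor(t(fc)), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(d$var_fraction, (ev / sum(ev))[seq_along(d$var_fraction)],
                 tolerance = 1e-9)
    # loadings columns unit norm, fractions non-increasing
    expect_equal(unname(colSums(d$loadings^2)),
                 rep(1, ncol(d$loadings)), tolerance = 1e-9)
    expect_true(all(diff(d$var_fraction) <= 1e-12))
    expect_lte(sum(d$var_fraction), 1 + 1e-9)
  }
})

test_that("sign orientation is deterministic and magnitude-preserving under global sign flips", {
  set.seed(6)
  fc <- planted_fc(c(8), 20, within_noise = 0.3, seed = 6)
  d1 <- decompose_module(fc, rownames(fc))
  d2 <- decompose_module(fc, rownames(fc))
  expect_identical(d1, d2)
  # orientation: summed correlation of each score with members is >= 0
  for (c in seq_len(ncol(d1$scores)))
    expect_gte(sum(cor(t(fc), d1$scores[, c])), -1e-9)
  # negating every member profile: orientation keeps summed score-member
  # correlation non-negative, so scores flip while loadings are preserved;
  # magnitudes are unchanged either way
  d_neg <- decompose_module(-fc, rownames(fc))
  expect_equal(abs(d_neg$scores), abs(d1$scores), tolerance = 1e-9)
  expect_equal(abs(d_neg$loadings), abs(d1$loadings), tolerance = 1e-9)
  for (c in seq_len(ncol(d_neg$scores)))
    expect_gte(sum(cor(t(-fc), d_neg$scores[, c])), -1e-9)
})

test_that("constant member genes and tiny modules are rejected", {
  fc <- rbind(g1 = rep(1, 5), g2 = c(1, 2, 3, 2, 1))
  colnames(fc) <- paste0("A", 1:5)
  expect_error(decompose_module(fc, c("g1", "g2")), "g1",
               class = "modstick_validation_error")
  expect_error(decompose_module(fc, "g2"),
               class = "modstick_validation_error")
})

test_that("virtual-gene matrix concatenates module-major with unit-variance columns", {
  set.seed(7)
  fc <- planted_fc(c(6, 5), 25, within_noise = 0.5, seed = 7)
  d1 <- decompose_module(fc, paste0("g", 1:6), module_id = 1L, n_pcs = 3L)
  d2 <- decompose_module(fc, paste0("g", 7:11), module_id = 2L, n_pcs = 2L)
  X <- build_virtual_gene_matrix(list(d1, d2))
  expect_identical(colnames(X), c("M1.PC1", "M1.PC2", "M1.PC3",
                                  "M2.PC1", "M2.PC2"))
  keys <- attr(X, "keys")
  expect_identical(keys$module, c(1L, 1L, 1L, 2L, 2L))
  expect_identical(keys$pc, c(1L, 2L, 3L, 1L, 2L))
  expect_equal(unname(apply(X, 2L, var)), rep(1, 5L), tolerance = 1e-9)

  # mismatched accession sets are rejected
  d3 <- decompose_module(fc[, 1:20], paste0("g", 7:11), module_id = 3L)
  expect_error(build_virtual_gene_matrix(list(d1, d3)),
               class = "modstick_validation_error")
})
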