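#' Synthetic-dataset settings
#'
#' Describes a fully synthetic paired (control/stress) count experiment
#' with known module structure: each module is driven by one dominant
#' latent accession pattern, and planted submodules add a secondary
#' pattern, orthogonal to the module's dominant one, to a subset of member
#' genes. The phenotype is a linear combination of the planted secondary
#' patterns plus noise, so the generating truth matches the estimand of
#' the pipeline (the phenotype loads on a non-leading module component).
#'
#' The default dimensions emulate the study design the pipeline targets:
#' 92 paired accessions and modules of a few dozen genes.
#'
#' @param n_accessions number of paired accessions.
#' @param module_sizes integer vector of module sizes (genes per module).
#' @param plants list of planted submodules, each a list with `module`
#'   (module index), `n_genes`, and `effect` (coefficient of the planted
#'   pattern in the phenotype).
#' @param n_background unassigned pure-noise genes appended after the
#'   modules.
#' @param base_mean mean normalized count of the control condition.
#' @param dispersion negative-binomial dispersion of the control counts
#'   (variance `mu + dispersion * mu^2`).
#' @param noise_sd phenotype noise standard deviation.
#' @param gene_noise_sd per-gene fold-change noise standard deviation
#'   around the latent patterns.
#' @param seed integer seed.
#' @return a `modstick_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_accessions = 92L,
                           module_sizes = c(60L, 40L, 30L),
                           plants = list(list(module = 1L, n_genes = 15L,
                                              effect = 0.5)),
                           n_background = 40L, base_mean = 200,
                           dispersion = 0.15, noise_sd = 0.1,
                           gene_noise_sd = 0.25, seed = 1L) {
  stopifnot_scalar_number(n_accessions, "n_accessions", min = 3)
  stopifnot_scalar_number(base_mean, "base_mean", min = 1e-9)
  stopifnot_scalar_number(dispersion, "dispersion", min = 1e-9)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(gene_noise_sd, "gene_noise_sd", min = 0)
  if (any(module_sizes < 2L))
    ms_stop("module sizes must be at least 2", "modstick_validation_error")
  for (p in plants) {
    if (p$module < 1L || p$module > length(module_sizes))
      ms_stop("plant refers to a nonexistent module", "modstick_validation_error")
    if (p$n_genes < 2L || p$n_genes > module_sizes[p$module])
      ms_stop("planted submodule size must be in [2, module size]",
              "modstick_validation_error")
  }
  if (anyDuplicated(vapply(plants, function(p) as.numeric(p$module), 0)))
    ms_stop("at most one planted submodule per module", "modstick_validation_error")
  structure(list(n_accessions = as.integer(n_accessions),
                 module_sizes = as.integer(module_sizes), plants = plants,
                 n_background = as.integer(n_background),
                 base_mean = base_mean, dispersion = dispersion,
                 noise_sd = noise_sd, gene_noise_sd = gene_noise_sd,
                 seed = as.integer(seed)),
            class = "modstick_synthetic_spec")
}

# Planted contribution profile for a q-gene submodule inside a K-gene
# module: the broken-stick order-statistic location-plus-2-sd curve of the
# K-piece null, restricted to ranks 1..q and normalized. Planting secondary
# weights proportional to the square root of this profile makes every
# planted gene an unambiguous "unusual contributor" (about 30% above the
# 95% null quantile at each rank), so the planted set is a well-defined
# ground truth for the contribution test rather than a borderline one.
planted_profile <- function(q, K) {
  i <- seq_len(K)
  esum <- rev(cumsum(rev(1 / i)))
  vsum <- rev(cumsum(rev(1 / i^2)))
  shape <- (esum[seq_len(q)] + 2 * sqrt(vsum[seq_len(q)])) / K
  shape / sum(shape)
}

orthogonalize <- function(v, basis) {
  if (length(basis)) {
    b <- do.call(cbind, basis)
    v <- v - b %*% solve(crossprod(b), crossprod(b, v))
  }
  drop(scale(v))
}

#' Generate a synthetic paired count dataset with planted structure
#'
#' Control counts are negative-binomial draws around `base_mean`; stress
#' counts are `control * 2^fc` where the log2 fold-change matrix `fc`
#' carries the module and submodule structure. Planted submodule genes mix
#' the module's dominant pattern with the plant's secondary pattern at
#' gene-specific angles following [a graded contribution
#' profile][synthetic_spec()]; the phenotype is the sum of
#' `effect * pattern` over plants plus Gaussian noise. Fully reproducible
#' from the seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a `modstick_expression`), `phenotype`
#'   (named vector), and `truth` (gene-to-module map, planted gene sets,
#'   latent patterns, true coefficients).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  n <- spec$n_accessions
  acc <- sprintf("ACC%03d", seq_len(n))
  n_mod <- length(spec$module_sizes)
  n_genes <- sum(spec$module_sizes) + spec$n_background
  genes <- sprintf("G%05d", seq_len(n_genes))

  primary <- lapply(seq_len(n_mod), function(m) drop(scale(stats::rnorm(n))))
  plant_patterns <- list()
  basis <- primary
  for (pi in seq_along(spec$plants)) {
    s <- orthogonalize(stats::rnorm(n), basis)
    plant_patterns[[pi]] <- s
    basis <- c(basis, list(s))
  }

  fc <- matrix(0, n_genes, n, dimnames = list(genes, acc))
  partition <- stats::setNames(integer(n_genes), genes)
  planted_sets <- vector("list", length(spec$plants))
  g0 <- 0L
  for (m in seq_len(n_mod)) {
    K <- spec$module_sizes[m]
    idx <- g0 + seq_len(K)
    partition[idx] <- m
    mix <- matrix(0, K, 2L)        # columns: primary weight, secondary weight
    mix[, 1L] <- 1
    plant_here <- which(vapply(spec$plants, function(p) p$module == m, TRUE))
    offset <- 0L
    for (pi in plant_here) {
      p <- spec$plants[[pi]]
      prof <- planted_profile(p$n_genes, K)
      rows <- offset + seq_len(p$n_genes)   # planted genes lead the module
      sin_phi <- 0.97 * sqrt(prof / prof[1L])
      # alternate the secondary-pattern sign across planted genes: the
      # contribution test is sign-blind (squared loadings), and a balanced
      # sign pattern keeps the primary and secondary gene-weight vectors
      # near-orthogonal, so the module PCA recovers the planted profile
      # without rotation leakage between PC1 and PC2
      mix[rows, 2L] <- sin_phi * (-1)^(seq_along(rows) - 1L)
      mix[rows, 1L] <- sqrt(1 - sin_phi^2)
      planted_sets[[pi]] <- genes[idx[rows]]
      offset <- offset + p$n_genes
    }
    pat <- cbind(primary[[m]],
                 if (length(plant_here))
                   plant_patterns[[plant_here[1L]]] else rep(0, n))
    for (k in seq_len(K)) {
      fc[idx[k], ] <- mix[k, 1L] * pat[, 1L] + mix[k, 2L] * pat[, 2L] +
        stats::rnorm(n, 0, spec$gene_noise_sd)
    }
    g0 <- g0 + K
  }
  if (spec$n_background > 0L) {
    idx <- g0 + seq_len(spec$n_background)
    fc[idx, ] <- stats::rnorm(spec$n_background * n, 0, 1)
  }

  mu <- exp(stats::rnorm(n_genes, log(spec$base_mean), 0.3))
  control <- matrix(stats::rnbinom(n_genes * n, mu = rep(mu, n),
                                   size = 1 / spec$dispersion),
                    n_genes, n)
  stress <- control * 2^fc
  counts <- cbind(control, stress)
  rownames(counts) <- genes
  colnames(counts) <- c(paste0(acc, "_C"), paste0(acc, "_S"))
  meta <- data.frame(sample_id = colnames(counts),
                     accession = rep(acc, 2L),
                     condition = rep(c("control", "stress"), each = n))

  y <- stats::rnorm(n, 0, spec$noise_sd)
  coefs <- numeric(length(spec$plants))
  for (pi in seq_along(spec$plants)) {
    coefs[pi] <- spec$plants[[pi]]$effect
    y <- y + coefs[pi] * plant_patterns[[pi]]
  }

  list(dataset = expression_dataset(counts, meta),
       phenotype = stats::setNames(y, acc),
       truth = list(partition = partition, planted_genes = planted_sets,
                    primary_patterns = primary,
                    plant_patterns = plant_patterns,
                    true_coefficients = coefs, fc = fc))
}

#' Generate a synthetic virtual-gene design matrix
#'
#' Columns with unit sample variance and a common pairwise population
#' correlation (0 gives near-orthogonal columns), built from a shared
#' latent factor; a synthetic stand-in for a real accessions x PCs design.
#' Column names follow the `M<module>.PC<j>` convention with three
#' components per module, so a 51-column matrix mimics 17 modules.
#'
#' @param n_samples rows.
#' @param n_columns columns.
#' @param column_correlation pairwise population correlation in `[0, 1)`.
#' @param seed integer seed.
#' @return n_samples x n_columns matrix, columns centered with unit sample
#'   variance.
#' @export
generate_design_matrix <- function(n_samples, n_columns,
                                   column_correlation = 0, seed = 1L) {
  stopifnot_scalar_number(n_columns, "n_columns", min = 1)
  if (!is.numeric(column_correlation) || column_correlation < 0 ||
      column_correlation >= 1)
    ms_stop("column_correlation must be in [0, 1)", "modstick_validation_error")
  set.seed(seed)
  z <- stats::rnorm(n_samples)
  X <- sqrt(column_correlation) * z +
    sqrt(1 - column_correlation) *
      matrix(stats::rnorm(n_samples * n_columns), n_samples, n_columns)
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  colnames(X) <- paste0("M", ceiling(seq_len(n_columns) / 3L), ".PC",
                        (seq_len(n_columns) - 1L) %% 3L + 1L)
  rownames(X) <- sprintf("S%03d", seq_len(n_samples))
  X
}
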