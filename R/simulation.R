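# Deterministic counter-based sub-seeding: the master seed and a counter
# fully determine every replicate's stream, independent of execution order.
sub_seed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 * 7919 +
              as.numeric(counter) * 104729) %% 2147483629) + 1L
}

#' Simulate a phenotype from a design matrix
#'
#' `y = X b + e` with `e ~ N(0, sigma^2)` i.i.d.; reproducible by seed.
#'
#' @param X samples x P design matrix.
#' @param beta coefficient vector, one entry per column of `X`.
#' @param sigma noise standard deviation.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return numeric phenotype vector of length `nrow(X)`.
#' @export
simulate_response <- function(X, beta, sigma, seed = NULL) {
  if (length(beta) != ncol(X))
    ms_stop("beta must have one entry per design column",
            "modstick_validation_error")
  if (!is.null(seed)) set.seed(seed)
  drop(X %*% beta) + stats::rnorm(nrow(X), 0, sigma)
}

#' Precision-recall AUC of a ranked feature list (average precision)
#'
#' Features are sorted by score in descending order (ties resolved by
#' stable input order) and the average-precision form is used: the mean,
#' over true positives, of the precision at each positive's depth.
#'
#' @param scores numeric score per feature (higher = ranked earlier).
#' @param truth logical flag per feature (at least one `TRUE`).
#' @return average precision in `(0, 1]`.
#' @export
pr_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (!any(truth))
    ms_stop("pr_auc requires at least one positive", "modstick_validation_error")
  if (length(scores) != length(truth))
    ms_stop("scores and truth must have equal length", "modstick_validation_error")
  ord <- order(-scores)  # stable: ties keep input order
  hits <- truth[ord]
  precision <- cumsum(hits) / seq_along(hits)
  mean(precision[hits])
}

#' Rank features by absolute correlation with the response
#'
#' @param X samples x P design matrix.
#' @param y response vector (non-constant).
#' @return list with `ranking` (feature names or indices, best first) and
#'   `scores` (absolute correlations, constant columns scored 0 with a
#'   warning).
#' @export
rank_by_correlation <- function(X, y) {
  if (stats::sd(y) == 0)
    ms_stop("response is constant", "modstick_validation_error")
  sds <- apply(X, 2L, stats::sd)
  r <- rep(0, ncol(X))
  if (any(sds == 0))
    ms_warn("constant design column(s) assigned correlation 0",
            "modstick_degenerate")
  ok <- sds > 0
  r[ok] <- abs(as.numeric(stats::cor(X[, ok, drop = FALSE], y)))
  nm <- colnames(X); if (is.null(nm)) nm <- as.character(seq_len(ncol(X)))
  list(ranking = nm[order(-r, seq_along(r))],
       scores = stats::setNames(r, nm))
}

#' Simulation settings
#'
#' Captures the two published simulation designs. Simulation I scales a set
#' of base coefficients on a fixed support by a grid of multiplying factors
#' (range 0.3 to 2). Simulation II assigns `+e` to four and `-e` to four
#' support columns over an effect-size grid (.03, .05, .08, .1, .15, .3,
#' .5), re-drawing the 8-column support per replicate by default
#' (`support_mode = "random"`); `support_mode = "fixed"` keeps
#' `true_support` with its sign pattern.
#'
#' @param X design matrix (real or from [generate_design_matrix()]).
#' @param true_support integer or character vector of true columns
#'   (Simulation I, and Simulation II with `support_mode = "fixed"`).
#' @param base_coefficients coefficients on the support (Simulation I).
#' @param factors multiplier grid for Simulation I (default 18 evenly
#'   spaced values from 0.3 to 2).
#' @param effect_sizes effect grid for Simulation II.
#' @param n_support support size for Simulation II random draws.
#' @param sigma noise standard deviation (default 0.1 on unit-variance
#'   columns).
#' @param n_rep replicates per setting.
#' @param seed master seed; every replicate derives a counter-based
#'   sub-seed from it.
#' @param support_mode `"random"` or `"fixed"` (Simulation II).
#' @param selection fitting configuration for the LASSO ranking (a
#'   [selection_config()]).
#' @return a `modstick_sim_spec` list.
#' @export
simulation_spec <- function(X, true_support = NULL, base_coefficients = NULL,
                            factors = seq(0.3, 2, length.out = 18L),
                            effect_sizes = c(.03, .05, .08, .1, .15, .3, .5),
                            n_support = 8L, sigma = 0.1, n_rep = 100L,
                            seed = 1L,
                            support_mode = c("random", "fixed"),
                            selection = selection_config()) {
  stopifnot_scalar_number(sigma, "sigma", min = 1e-12)
  stopifnot_scalar_number(n_rep, "n_rep", min = 1)
  structure(list(X = as.matrix(X), true_support = true_support,
                 base_coefficients = base_coefficients, factors = factors,
                 effect_sizes = effect_sizes, n_support = as.integer(n_support),
                 sigma = sigma, n_rep = as.integer(n_rep),
                 seed = as.integer(seed),
                 support_mode = match.arg(support_mode),
                 selection = selection),
            class = "modstick_sim_spec")
}

support_index <- function(X, support) {
  if (is.character(support)) match(support, colnames(X)) else as.integer(support)
}

run_one_setting <- function(spec, setting, beta_fun, counter0) {
  X <- spec$X; P <- ncol(X)
  nm <- colnames(X); if (is.null(nm)) nm <- as.character(seq_len(P))
  out <- vector("list", spec$n_rep)
  for (r in seq_len(spec$n_rep)) {
    s <- sub_seed(spec$seed, counter0 + r)
    set.seed(s)
    bt <- beta_fun()                 # may consume RNG (random support)
    y <- drop(X %*% bt$beta) + stats::rnorm(nrow(X), 0, spec$sigma)
    fit <- select_virtual_genes(X, y, spec$selection)
    lasso_rank <- fit$ranking
    lasso_scores <- stats::setNames(P - match(nm, lasso_rank) + 1L, nm)
    corr_scores <- rank_by_correlation(X, y)$scores
    truth <- stats::setNames(seq_len(P) %in% bt$support, nm)
    out[[r]] <- data.frame(setting = setting, replicate = r,
                           method = c("lasso_path", "correlation"),
                           pr_auc = c(pr_auc(lasso_scores, truth),
                                      pr_auc(corr_scores, truth)),
                           seed = s)
  }
  do.call(rbind, out)
}

#' Simulation I: scaled real-support coefficients
#'
#' For each multiplying factor the support coefficients are `factor *
#' base_coefficients` (zeros elsewhere), the phenotype is simulated, and
#' both rankings (shrinkage path via a fresh penalized fit, and absolute
#' correlation) are scored by PR AUC against the support.
#'
#' @param spec a [simulation_spec()] with `true_support` and
#'   `base_coefficients`.
#' @return a `modstick_sim_result`: data.frame (setting, replicate, method,
#'   pr_auc, seed) with attribute `"mode" = "I"`.
#' @export
run_simulation_I <- function(spec) {
  if (is.null(spec$true_support) || !length(spec$true_support))
    ms_stop("Simulation I requires a non-empty true_support",
            "modstick_validation_error")
  idx <- support_index(spec$X, spec$true_support)
  if (length(idx) != length(spec$base_coefficients))
    ms_stop("base_coefficients must match true_support",
            "modstick_validation_error")
  P <- ncol(spec$X)
  res <- list()
  for (fi in seq_along(spec$factors)) {
    f <- spec$factors[fi]
    beta_fun <- function() {
      b <- numeric(P); b[idx] <- f * spec$base_coefficients
      list(beta = b, support = idx)
    }
    res[[fi]] <- run_one_setting(spec, f, beta_fun, (fi - 1L) * spec$n_rep)
  }
  structure(do.call(rbind, res), mode = "I", class = c("modstick_sim_result",
                                                       "data.frame"))
}

#' Simulation II: +/- effect pattern on a (re-)drawn support
#'
#' For each effect size e, eight support columns carry coefficients `+e`
#' (four) and `-e` (four); by default the support is re-drawn uniformly at
#' random per replicate.
#'
#' @param spec a [simulation_spec()].
#' @return a `modstick_sim_result` data.frame with attribute
#'   `"mode" = "II"`.
#' @export
run_simulation_II <- function(spec) {
  P <- ncol(spec$X)
  k <- spec$n_support
  if (P < k)
    ms_stop(sprintf("design has %d columns but %d support columns requested",
                    P, k), "modstick_validation_error")
  if (k %% 2L != 0L)
    ms_stop("n_support must be even (half positive, half negative)",
            "modstick_validation_error")
  fixed_idx <- if (spec$support_mode == "fixed") {
    if (is.null(spec$true_support))
      ms_stop("support_mode = 'fixed' requires true_support",
              "modstick_validation_error")
    support_index(spec$X, spec$true_support)
  }
  res <- list()
  for (ei in seq_along(spec$effect_sizes)) {
    e <- spec$effect_sizes[ei]
    beta_fun <- function() {
      idx <- if (is.null(fixed_idx)) sample.int(P, k) else fixed_idx
      b <- numeric(P)
      b[idx] <- rep(c(e, -e), each = length(idx) / 2L)
      list(beta = b, support = idx)
    }
    res[[ei]] <- run_one_setting(spec, e, beta_fun, (ei - 1L) * spec$n_rep)
  }
  structure(do.call(rbind, res), mode = "II", class = c("modstick_sim_result",
                                                        "data.frame"))
}

#' Paired method comparison per setting
#'
#' Two-sided Wilcoxon signed-rank test of the paired per-replicate PR AUC
#' values (shrinkage path vs correlation) at each setting, with the usual
#' significance labels (* p < .05, ** p < .01, *** p < .001).
#'
#' @param result a `modstick_sim_result`.
#' @return data.frame (setting, median_lasso, median_correlation, p_value,
#'   label).
#' @export
compare_methods <- function(result) {
  settings <- sort(unique(result$setting))
  rows <- lapply(settings, function(s) {
    d <- result[result$setting == s, ]
    a <- d$pr_auc[d$method == "lasso_path"][order(d$replicate[d$method == "lasso_path"])]
    b <- d$pr_auc[d$method == "correlation"][order(d$replicate[d$method == "correlation"])]
    if (length(a) != length(b))
      ms_stop("unpaired replicates in comparison", "modstick_validation_error")
    p <- if (all(a == b)) {
      ms_warn(sprintf("all paired differences zero at setting %s", s),
              "modstick_degenerate")
      1
    } else {
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                          alternative = "two.sided"))$p.value
    }
    data.frame(setting = s, median_lasso = stats::median(a),
               median_correlation = stats::median(b), p_value = p,
               label = if (p < .001) "***" else if (p < .01) "**"
                       else if (p < .05) "*" else "")
  })
  do.call(rbind, rows)
}
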