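#' Penalized-selection configuration
#'
#' The phenotype is regressed on the virtual genes with an elastic-net
#' penalty, `alpha = 1` (pure LASSO) by default; the penalty strength is
#' chosen by leave-one-out cross-validation under the one-standard-error
#' rule (the most regularized model whose CV error is within one standard
#' error of the minimum).
#'
#' @param alpha elastic-net mixing in `[0, 1]` (1 = LASSO, 0 = ridge).
#' @param n_lambda number of penalty grid points.
#' @param lambda_min_ratio grid floor as a fraction of `lambda_max`.
#' @param rule `"one_se"` (default) or `"min"`.
#' @param standardize standardize design columns to unit sample variance
#'   before fitting (coefficients are reported on that scale).
#' @param thresh coordinate-descent convergence threshold.
#' @return a `modstick_selection_config` list.
#' @export
selection_config <- function(alpha = 1, n_lambda = 100L,
                             lambda_min_ratio = 1e-4,
                             rule = c("one_se", "min"), standardize = TRUE,
                             thresh = 1e-9) {
  stopifnot_scalar_number(alpha, "alpha", min = 0, max = 1)
  stopifnot_scalar_number(n_lambda, "n_lambda", min = 2)
  stopifnot_scalar_number(lambda_min_ratio, "lambda_min_ratio",
                          min = 1e-12, max = 1)
  structure(list(alpha = alpha, n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 rule = match.arg(rule), standardize = isTRUE(standardize),
                 thresh = thresh),
            class = "modstick_selection_config")
}

align_xy <- function(X, y) {
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    if (!setequal(names(y), rownames(X)))
      ms_stop("accession sets of design matrix and phenotype differ",
              "modstick_validation_error")
    y <- y[rownames(X)]
  } else if (length(y) != nrow(X)) {
    ms_stop("phenotype length does not match design rows",
            "modstick_validation_error")
  }
  if (any(!is.finite(y)))
    ms_stop("phenotype contains non-finite values", "modstick_validation_error")
  list(X = X, y = as.numeric(y))
}

prepare_design <- function(X, cfg) {
  X <- as.matrix(X)
  if (cfg$standardize) {
    sds <- apply(X, 2L, stats::sd)
    drop <- sds == 0
    if (any(drop)) {
      ms_warn(paste0("dropping zero-variance column(s): ",
                     paste(colnames(X)[drop], collapse = ", ")),
              "modstick_degenerate")
      X <- X[, !drop, drop = FALSE]
      sds <- sds[!drop]
    }
    X <- scale(X, center = TRUE, scale = sds)
  }
  X
}

lambda_grid <- function(X, y, cfg) {
  n <- nrow(X)
  a <- max(cfg$alpha, 1e-3)  # ridge limit: conventional finite grid anchor
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / (n * a)
  if (lam_max <= 0) lam_max <- 1e-3
  exp(seq(log(lam_max), log(lam_max * cfg$lambda_min_ratio),
          length.out = cfg$n_lambda))
}

glmnet_path <- function(X, y, grid, cfg) {
  glmnet::glmnet(X, y, family = "gaussian", alpha = cfg$alpha,
                 lambda = grid, standardize = FALSE, intercept = TRUE,
                 thresh = cfg$thresh, maxit = 1e7)
}

#' Fit the elastic-net coefficient path
#'
#' Solves `(1/(2n)) * RSS + lambda * (alpha * ||b||_1 + (1-alpha)/2 *
#' ||b||_2^2)` (intercept unpenalized) over a log-spaced grid of `n_lambda`
#' penalties from `lambda_max` (the smallest penalty with an all-zero
#' solution, `max_j |x_j' (y - mean(y))| / (n * alpha)`) down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @param X accessions x P design matrix (e.g. from
#'   [build_virtual_gene_matrix()]).
#' @param y named phenotype vector, aligned to `X` rows by accession name
#'   when names are present.
#' @param cfg a [selection_config()].
#' @return a `modstick_selection` object holding the grid, the coefficient
#'   path (`path`, P x n_lambda), intercepts, and the inputs needed by
#'   [loo_cv()] and [select_lambda()].
#' @export
fit_elastic_net_path <- function(X, y, cfg = selection_config()) {
  al <- align_xy(X, y)
  keys <- vgm_keys(al$X)
  Xs <- prepare_design(al$X, cfg)
  y <- al$y
  if (nrow(Xs) < 3L)
    ms_stop("at least 3 samples are required", "modstick_validation_error")
  grid <- lambda_grid(Xs, y, cfg)
  fit <- glmnet_path(Xs, y, grid, cfg)
  path <- as.matrix(fit$beta)
  structure(list(lambda_grid = grid, path = path, intercepts = fit$a0,
                 feature_names = colnames(Xs),
                 keys = keys[colnames(Xs), , drop = FALSE],
                 X = Xs, y = y, config = cfg,
                 cv_mse = NULL, cv_se = NULL,
                 lambda_min = NULL, lambda_chosen = NULL,
                 coefficients = NULL, selected = NULL, ranking = NULL),
            class = "modstick_selection")
}

#' Leave-one-out cross-validation of the penalty
#'
#' For each sample i the path is refit on the remaining n-1 samples over
#' the same penalty grid and the squared prediction error for sample i is
#' recorded at every grid point. `cv_mse` is the mean over samples,
#' `cv_se` the standard deviation over samples divided by `sqrt(n)`.
#' Leave-one-out CV is deterministic: there is no fold randomness.
#'
#' @param fit a `modstick_selection` from [fit_elastic_net_path()].
#' @param cfg a [selection_config()] (defaults to the one stored in `fit`).
#' @return `fit` with `cv_mse`, `cv_se` and `lambda_min` filled in.
#' @export
loo_cv <- function(fit, cfg = fit$config) {
  X <- fit$X; y <- fit$y; grid <- fit$lambda_grid
  n <- nrow(X)
  err <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    fi <- glmnet_path(X[-i, , drop = FALSE], y[-i], grid, cfg)
    pred <- drop(X[i, , drop = FALSE] %*% as.matrix(fi$beta)) + fi$a0
    err[i, ] <- (y[i] - pred)^2
  }
  fit$cv_mse <- colMeans(err)
  fit$cv_se <- apply(err, 2L, stats::sd) / sqrt(n)
  fit$lambda_min <- grid[which.min(fit$cv_mse)]
  fit
}

#' Choose the penalty and extract the selected set
#'
#' `rule = "one_se"` picks the largest penalty whose CV error is within one
#' standard error of the minimum; `rule = "min"` picks the CV minimizer.
#' Coefficients and the selected (module, pc) set are read off the path at
#' the chosen penalty, and the path-based feature ranking is attached.
#'
#' @param fit a `modstick_selection` with CV results (see [loo_cv()]).
#' @param cfg a [selection_config()]; its `rule` is used.
#' @return `fit` with `lambda_chosen`, `coefficients`, `selected` and
#'   `ranking` filled in.
#' @export
select_lambda <- function(fit, cfg = fit$config) {
  if (is.null(fit$cv_mse))
    ms_stop("run loo_cv() before select_lambda()", "modstick_validation_error")
  grid <- fit$lambda_grid
  i_min <- which.min(fit$cv_mse)
  fit$lambda_min <- grid[i_min]
  i_chosen <- if (cfg$rule == "one_se") {
    bound <- fit$cv_mse[i_min] + fit$cv_se[i_min]
    min(which(fit$cv_mse <= bound))  # grid is descending: smallest index = largest lambda
  } else i_min
  fit$lambda_chosen <- grid[i_chosen]
  coefs <- stats::setNames(fit$path[, i_chosen], fit$feature_names)
  fit$coefficients <- coefs
  fit$selected <- fit$feature_names[coefs != 0]
  fit$ranking <- rank_features_by_path(fit)
  fit
}

#' Rank features by shrinkage-path survival
#'
#' Features are ordered by the largest grid penalty at which their path
#' coefficient is nonzero (surviving a stronger penalty ranks higher);
#' features tied at the same entry point are ordered by absolute
#' coefficient at the chosen penalty (falling back to the smallest grid
#' penalty when no choice has been made), then by column order.
#'
#' @param fit a `modstick_selection` with the path computed.
#' @return character vector of feature names, best first.
#' @export
rank_features_by_path <- function(fit) {
  path <- fit$path; grid <- fit$lambda_grid
  entry <- apply(path != 0, 1L, function(nz)
    if (any(nz)) grid[min(which(nz))] else -Inf)
  ref_col <- if (!is.null(fit$lambda_chosen))
    which.min(abs(grid - fit$lambda_chosen)) else length(grid)
  tie <- abs(path[, ref_col])
  fit$feature_names[order(-entry, -tie, seq_along(entry))]
}

#' Fit, cross-validate and select in one call
#' @inheritParams fit_elastic_net_path
#' @return a complete `modstick_selection` object.
#' @export
select_virtual_genes <- function(X, y, cfg = selection_config()) {
  select_lambda(loo_cv(fit_elastic_net_path(X, y, cfg), cfg), cfg)
}

#' @export
print.modstick_selection <- function(x, ...) {
  cat(sprintf("penalized selection over %d features, %d-point grid\n",
              nrow(x$path), length(x$lambda_grid)))
  if (!is.null(x$lambda_chosen)) {
    cat(sprintf("  lambda_min = %.5g, lambda_chosen = %.5g (rule: %s)\n",
                x$lambda_min, x$lambda_chosen, x$config$rule))
    cat(sprintf("  selected: %s\n",
                if (length(x$selected)) paste(x$selected, collapse = ", ")
                else "(none)"))
  }
  invisible(x)
}
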