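#' Gene contributions to a module component
#'
#' A gene's contribution to a component is its squared loading entry; with
#' unit-norm eigenvectors the contributions over the module sum to 1,
#' matching the unit stick of the broken-stick null.
#'
#' @param decomp a `modstick_decomposition`.
#' @param pc_index which retained component (1-based).
#' @return a `modstick_contributions`: list with `module_id`, `pc_index`,
#'   `gene_ids`, `contributions` (named, summing to 1).
#' @export
gene_contributions <- function(decomp, pc_index) {
  j <- ncol(decomp$loadings)
  if (!is.numeric(pc_index) || length(pc_index) != 1L ||
      pc_index < 1L || pc_index > j)
    ms_stop(sprintf("pc_index must be in 1..%d", j),
            "modstick_validation_error")
  contrib <- decomp$loadings[, pc_index]^2
  structure(list(module_id = decomp$module_id, pc_index = as.integer(pc_index),
                 gene_ids = decomp$gene_ids,
                 contributions = stats::setNames(contrib, decomp$gene_ids)),
            class = "modstick_contributions")
}

#' Broken-stick (uniform Dirichlet) null thresholds
#'
#' Draws `n_draws` samples of a unit stick broken uniformly at random into
#' `K` pieces (a flat Dirichlet, sampled as K independent standard
#' exponentials normalized by their sum), sorts each sample's pieces in
#' descending order, and records the `quantile`-level value of each sorted
#' piece's empirical distribution. Thresholds are non-increasing in rank.
#' The draw is bit-reproducible given `seed`.
#'
#' @param K number of pieces (module size).
#' @param n_draws Monte-Carlo sample size (default 10000).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param quantile upper quantile level of the null (default 0.95).
#' @return a `modstick_broken_stick_null`: list with `K`, `n_draws`,
#'   `seed`, `quantile`, `thresholds` (length K).
#' @export
broken_stick_null <- function(K, n_draws = 10000L, seed = NULL,
                              quantile = 0.95) {
  stopifnot_scalar_number(K, "K", min = 1)
  stopifnot_scalar_number(n_draws, "n_draws", min = 1)
  stopifnot_scalar_number(quantile, "quantile", min = 0, max = 1)
  K <- as.integer(K)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (K == 1L) {
    thr <- 1
  } else {
    e <- matrix(stats::rexp(n_draws * K), n_draws, K)
    e <- e / rowSums(e)
    sorted <- apply(e, 1L, sort, decreasing = TRUE)  # K x n_draws
    thr <- apply(sorted, 1L, stats::quantile, probs = quantile, names = FALSE)
  }
  structure(list(K = K, n_draws = as.integer(n_draws), seed = seed,
                 quantile = quantile, thresholds = thr),
            class = "modstick_broken_stick_null")
}

#' Test genes for unusual contribution to a component
#'
#' Contributions are sorted in descending order and the m-th largest is
#' compared against the null quantile of the m-th largest broken-stick
#' piece. Under the default contiguous rule the walk down the ranks stops
#' at the first non-significant rank, yielding a contiguous top set;
#' `rule = "all"` tests every rank independently.
#'
#' @param contrib a [gene_contributions()] result.
#' @param null a [broken_stick_null()] with matching `K`.
#' @param rule `"contiguous"` (default) or `"all"`.
#' @param correlations optional named per-gene correlations with the PC
#'   score (reporting only; see [gene_pc_correlation()]).
#' @return a `modstick_broken_stick`: list with `module_id`, `pc_index`,
#'   `quantile`, `n_tests`, and `table`, a data.frame (gene_id,
#'   contribution, rank, threshold, significant, correlation) sorted by
#'   rank.
#' @export
test_genes <- function(contrib, null, rule = c("contiguous", "all"),
                       correlations = NULL) {
  rule <- match.arg(rule)
  K <- length(contrib$contributions)
  if (null$K != K)
    ms_stop(sprintf("null was built for K = %d but module has %d genes",
                    null$K, K), "modstick_validation_error")
  ord <- order(-contrib$contributions, seq_len(K))
  sorted <- contrib$contributions[ord]
  exceeds <- sorted > null$thresholds
  sig <- if (rule == "contiguous") {
    first_fail <- if (all(exceeds)) K + 1L else min(which(!exceeds))
    seq_len(K) < first_fail
  } else exceeds
  tab <- data.frame(gene_id = names(sorted),
                    contribution = unname(sorted),
                    rank = seq_len(K),
                    threshold = null$thresholds,
                    significant = sig,
                    row.names = NULL)
  if (!is.null(correlations))
    tab$correlation <- unname(correlations[tab$gene_id])
  structure(list(module_id = contrib$module_id, pc_index = contrib$pc_index,
                 quantile = null$quantile, n_tests = K, rule = rule,
                 table = tab),
            class = "modstick_broken_stick")
}

#' @export
print.modstick_broken_stick <- function(x, ...) {
  cat(sprintf("broken-stick test, module %s PC%d: %d / %d genes significant at the %.0f%% null quantile\n",
              x$module_id, x$pc_index, sum(x$table$significant), x$n_tests,
              100 * x$quantile))
  invisible(x)
}

#' Correlation of member genes with a component score
#'
#' Pearson correlation of each member gene's fold-change profile with the
#' component score vector; reported alongside the broken-stick flags (the
#' selected genes of a second or third component typically form a separate
#' high-correlation peak).
#'
#' @param fc genes x accessions fold-change matrix.
#' @param members member gene ids (subset of `rownames(fc)`).
#' @param pc_score numeric score vector, one value per accession.
#' @return named numeric vector of correlations.
#' @export
gene_pc_correlation <- function(fc, members, pc_score) {
  missing <- setdiff(members, rownames(fc))
  if (length(missing))
    ms_stop(paste0("gene(s) absent from fold-change matrix: ",
                   paste(missing, collapse = ", ")),
            "modstick_validation_error")
  x <- t(fc[members, , drop = FALSE])
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    ms_stop(paste0("constant profile for gene(s): ",
                   paste(members[sds == 0], collapse = ", ")),
            "modstick_validation_error")
  stats::setNames(as.numeric(stats::cor(x, pc_score)), members)
}
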