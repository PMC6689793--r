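#' Co-expression network configuration
#'
#' Defaults follow the pipeline's published settings: soft-thresholding
#' power 4 (chosen so the scale-free topology fit exceeds 0.9 on the real
#' data), unsigned Pearson-correlation adjacency, minimum module size 25.
#' Module detection is a simplified static-height cut of the average-linkage
#' tree on topological-overlap dissimilarity; a precomputed partition can be
#' supplied instead wherever a partition is consumed.
#'
#' @param soft_power positive integer exponent on the absolute correlation.
#' @param min_module_size smallest cluster reported as a module.
#' @param cut_height static cut height on the dissimilarity dendrogram,
#'   in (0, 1]. The default 0.95 requires an average topological overlap of
#'   at least 0.05 within a module, which keeps isolated noise genes out of
#'   modules under a static cut.
#' @param unsigned if `TRUE` (default) adjacency uses `|cor|`; if `FALSE`,
#'   `((1 + cor)/2)^power` (signed network).
#' @param n_scalefree_bins connectivity bins for [scale_free_fit()].
#' @return a `modstick_network_config` list.
#' @export
network_config <- function(soft_power = 4L, min_module_size = 25L,
                           cut_height = 0.95, unsigned = TRUE,
                           n_scalefree_bins = 10L) {
  stopifnot_scalar_number(soft_power, "soft_power", min = 1)
  stopifnot_scalar_number(min_module_size, "min_module_size", min = 2)
  stopifnot_scalar_number(cut_height, "cut_height", min = 1e-12, max = 1)
  stopifnot_scalar_number(n_scalefree_bins, "n_scalefree_bins", min = 2)
  structure(list(soft_power = as.integer(soft_power),
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, unsigned = isTRUE(unsigned),
                 n_scalefree_bins = as.integer(n_scalefree_bins)),
            class = "modstick_network_config")
}

#' Soft-power weighted adjacency
#'
#' `a_ij = |cor(g_i, g_j)|^power` between gene fold-change profiles
#' (unsigned network); the diagonal is 1.
#'
#' @param fc genes x accessions log2 fold-change matrix (no constant rows).
#' @param cfg a [network_config()].
#' @return symmetric genes x genes adjacency matrix in `[0, 1]`.
#' @export
compute_adjacency <- function(fc, cfg = network_config()) {
  if (ncol(fc) < 3L)
    ms_stop("at least 3 accessions are required", "modstick_validation_error")
  sds <- apply(fc, 1L, stats::sd)
  if (any(sds == 0))
    ms_stop(paste0("constant fold-change profile, correlation undefined for gene(s): ",
                   paste(rownames(fc)[sds == 0], collapse = ", ")),
            "modstick_validation_error")
  cc <- stats::cor(t(fc))
  a <- if (cfg$unsigned) abs(cc)^cfg$soft_power else ((1 + cc) / 2)^cfg$soft_power
  a[a > 1] <- 1  # guard against rounding above 1
  diag(a) <- 1
  a <- (a + t(a)) / 2
  a
}

#' Topological overlap matrix
#'
#' Standard unsigned topological overlap:
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and connectivity
#' `k_i = sum_{u != i} a_iu`; `w_ii = 1`.
#'
#' @param adjacency symmetric adjacency in `[0, 1]` with unit diagonal.
#' @return symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
compute_tom <- function(adjacency) {
  a <- adjacency
  # (A^2)_ij counts u = i and u = j with a_ii = a_jj = 1
  l <- a %*% a - 2 * a
  k <- rowSums(a) - 1
  kmin <- outer(k, k, pmin)
  w <- (l + a) / (kmin + 1 - a)
  diag(w) <- 1
  w[w < 0] <- 0
  w <- (w + t(w)) / 2
  dimnames(w) <- dimnames(a)
  w
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at a static height; clusters smaller than `min_module_size` are
#' labeled 0 (unassigned) and surviving clusters are relabeled 1..M in
#' decreasing size order (ties broken by the lowest member gene index).
#' The result is deterministic given the input.
#'
#' @param tom topological overlap matrix (from [compute_tom()]).
#' @param cfg a [network_config()].
#' @return named integer vector of module labels (0 = unassigned).
#' @export
detect_modules <- function(tom, cfg = network_config()) {
  n <- nrow(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (n < cfg$min_module_size) {
    ms_warn("fewer genes than min_module_size; all genes unassigned",
            "modstick_empty_result")
    return(stats::setNames(integer(n), genes))
  }
  d <- stats::as.dist(1 - tom)
  h <- stats::hclust(d, method = "average")
  raw <- stats::cutree(h, h = cfg$cut_height)
  relabel_partition(stats::setNames(raw, genes), cfg$min_module_size)
}

# Relabel clusters 1..M in decreasing size order (ties: lowest member
# index first); clusters below the size floor become 0.
relabel_partition <- function(raw, min_module_size) {
  sizes <- table(raw)
  keep_ids <- names(sizes)[sizes >= min_module_size]
  first_idx <- vapply(keep_ids, function(id) min(which(raw == id)), 0L)
  ord <- keep_ids[order(-as.integer(sizes[keep_ids]), first_idx)]
  out <- integer(length(raw))
  for (m in seq_along(ord)) out[raw == ord[m]] <- m
  stats::setNames(out, names(raw))
}

#' Module membership as a list of gene-id vectors
#' @param partition named integer vector of module labels.
#' @return list indexed by module (1..M) of member gene ids.
#' @export
module_members <- function(partition) {
  m <- max(partition)
  if (m == 0L) return(list())
  lapply(seq_len(m), function(k) names(partition)[partition == k])
}

#' Scale-free topology fit index
#'
#' R-squared of the regression of `log10(freq(k))` on `log10(k)` over
#' equal-width connectivity bins; used diagnostically to assess whether the
#' chosen soft power yields an approximately scale-free network (the real
#' data target is a fit above 0.9 at power 4).
#'
#' @param adjacency adjacency matrix, or a precomputed vector of node
#'   connectivities.
#' @param cfg a [network_config()].
#' @return R-squared in `[0, 1]`; 0 with a warning for degenerate binning.
#' @export
scale_free_fit <- function(adjacency, cfg = network_config()) {
  k <- if (is.matrix(adjacency)) rowSums(adjacency) - 1
       else as.numeric(adjacency)
  if (diff(range(k)) < 1e-12) {
    ms_warn("all connectivities equal; scale-free fit undefined",
            "modstick_degenerate")
    return(0)
  }
  breaks <- seq(min(k), max(k), length.out = cfg$n_scalefree_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mid <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & mid > 0
  if (sum(ok) < 3L) {
    ms_warn("too few occupied connectivity bins for a scale-free fit",
            "modstick_degenerate")
    return(0)
  }
  fit <- stats::lm(log10(freq[ok] / sum(freq[ok])) ~ log10(mid[ok]))
  summary(fit)$r.squared
}
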