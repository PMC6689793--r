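#' Principal-component decomposition of one module
#'
#' Member genes' fold-change profiles are standardized (mean 0, unit
#' variance across accessions) and a PCA is run with genes as variables
#' (correlation PCA). The top `n_pcs` component score vectors are the
#' module's "virtual genes"; loadings are the unit-norm eigenvector entries
#' per gene and variance fractions are eigenvalues normalized by the trace.
#' Each component's sign is oriented so that the summed correlation between
#' its score vector and the member gene profiles is non-negative, removing
#' the eigenvector sign ambiguity.
#'
#' @param fc genes x accessions log2 fold-change matrix.
#' @param members character vector of member gene ids (at least 2).
#' @param module_id integer module label (metadata only).
#' @param n_pcs number of components to retain (capped at the matrix rank).
#' @param scale. if `TRUE` (default) genes are scaled to unit variance
#'   before PCA (correlation PCA); `FALSE` gives covariance PCA.
#' @return a `modstick_decomposition`: list with `module_id`, `gene_ids`,
#'   `accession_ids`, `scores` (accessions x j), `loadings` (genes x j,
#'   unit-norm columns), `var_fraction` (length j, non-increasing).
#' @export
decompose_module <- function(fc, members, module_id = NA_integer_,
                             n_pcs = 3L, scale. = TRUE) {
  if (length(members) < 2L)
    ms_stop("a module needs at least 2 genes", "modstick_validation_error")
  missing <- setdiff(members, rownames(fc))
  if (length(missing))
    ms_stop(paste0("member gene(s) absent from fold-change matrix: ",
                   paste(missing, collapse = ", ")),
            "modstick_validation_error")
  if (ncol(fc) < 3L)
    ms_stop("at least 3 accessions are required", "modstick_validation_error")
  x <- t(fc[members, , drop = FALSE])  # accessions x genes
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    ms_stop(paste0("constant profile for gene(s): ",
                   paste(members[sds == 0], collapse = ", ")),
            "modstick_validation_error")
  x <- scale(x, center = TRUE, scale = scale.)
  sv <- svd(x)
  tot_var <- sum(sv$d^2)
  rank <- sum(sv$d > max(sv$d) * 1e-9)
  j <- min(n_pcs, rank)
  loadings <- sv$v[, seq_len(j), drop = FALSE]
  scores <- sv$u[, seq_len(j), drop = FALSE] %*%
    diag(sv$d[seq_len(j)], j, j)
  # sign orientation: summed correlation between score and member profiles
  for (c in seq_len(j)) {
    s <- sum(stats::cor(x, scores[, c]))
    if (s < 0 || (s == 0 && loadings[which.max(abs(loadings[, c])), c] < 0)) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  dimnames(loadings) <- list(members, paste0("PC", seq_len(j)))
  dimnames(scores) <- list(colnames(fc), paste0("PC", seq_len(j)))
  structure(list(module_id = module_id, gene_ids = members,
                 accession_ids = colnames(fc), scores = scores,
                 loadings = loadings,
                 var_fraction = sv$d[seq_len(j)]^2 / tot_var),
            class = "modstick_decomposition")
}

#' @export
print.modstick_decomposition <- function(x, ...) {
  cat(sprintf("module %s: %d genes, %d PCs (variance fractions: %s)\n",
              x$module_id, length(x$gene_ids), ncol(x$scores),
              paste(sprintf("%.3f", x$var_fraction), collapse = ", ")))
  invisible(x)
}

#' Decompose every module of a partition
#' @param fc genes x accessions fold-change matrix.
#' @param partition named integer vector of module labels.
#' @param n_pcs components per module.
#' @param scale. passed to [decompose_module()].
#' @return list of `modstick_decomposition` objects, one per module 1..M.
#' @export
decompose_all_modules <- function(fc, partition, n_pcs = 3L, scale. = TRUE) {
  mem <- module_members(partition)
  lapply(seq_along(mem), function(k)
    decompose_module(fc, mem[[k]], module_id = k, n_pcs = n_pcs,
                     scale. = scale.))
}

#' Assemble the virtual-gene design matrix
#'
#' Concatenates the PC score vectors of all module decompositions,
#' module-major / component-minor (columns named `M<module>.PC<j>`), and
#' standardizes each column to mean 0 and unit sample variance so a single
#' penalty applies on one scale across components.
#'
#' @param decomps list of `modstick_decomposition` objects sharing one
#'   accession set and order.
#' @return accessions x P numeric matrix with attribute `"keys"`, a
#'   data.frame of (module, pc) per column.
#' @export
build_virtual_gene_matrix <- function(decomps) {
  if (!length(decomps))
    ms_stop("no module decompositions supplied", "modstick_validation_error")
  acc <- decomps[[1L]]$accession_ids
  for (d in decomps)
    if (!identical(d$accession_ids, acc))
      ms_stop("decompositions do not share the accession set and order",
              "modstick_validation_error")
  cols <- list(); keys <- list()
  for (d in decomps) {
    for (c in seq_len(ncol(d$scores))) {
      v <- d$scores[, c]
      cols[[length(cols) + 1L]] <-
        (v - mean(v)) / stats::sd(v)
      keys[[length(keys) + 1L]] <- c(d$module_id, c)
    }
  }
  x <- do.call(cbind, cols)
  km <- do.call(rbind, keys)
  colnames(x) <- paste0("M", km[, 1L], ".PC", km[, 2L])
  if (anyDuplicated(colnames(x)))
    ms_stop("duplicate (module, pc) keys across decompositions",
            "modstick_validation_error")
  rownames(x) <- acc
  attr(x, "keys") <- data.frame(module = km[, 1L], pc = km[, 2L],
                                row.names = colnames(x))
  x
}

vgm_keys <- function(X) {
  k <- attr(X, "keys")
  if (is.null(k)) {
    # reconstruct from column names of the M<k>.PC<j> form when possible
    m <- regmatches(colnames(X),
                    regexec("^M([0-9]+)\\.PC([0-9]+)$", colnames(X)))
    ok <- lengths(m) == 3L
    k <- data.frame(module = ifelse(ok, as.integer(vapply(m, function(z)
                      if (length(z) == 3L) z[2L] else NA_character_, "")), NA),
                    pc = ifelse(ok, as.integer(vapply(m, function(z)
                      if (length(z) == 3L) z[3L] else NA_character_, "")), NA),
                    row.names = colnames(X))
  }
  k
}
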