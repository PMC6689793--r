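# Small fixtures built in code, shared across test files.

toy_counts <- function(values, n_genes, n_samples,
                       genes = paste0("g", seq_len(n_genes)),
                       samples = paste0("s", seq_len(n_samples))) {
  matrix(values, n_genes, n_samples, dimnames = list(genes, samples))
}

toy_meta <- function(n_acc, acc = paste0("A", seq_len(n_acc))) {
  data.frame(sample_id = c(paste0(acc, "_c"), paste0(acc, "_s")),
             accession = rep(acc, 2L),
             condition = rep(c("control", "stress"), each = n_acc))
}

# paired dataset: columns ordered control block then stress block
toy_dataset <- function(control, stress) {
  n_acc <- ncol(control)
  meta <- toy_meta(n_acc)
  counts <- cbind(control, stress)
  colnames(counts) <- meta$sample_id
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  expression_dataset(counts, meta)
}

# fold-change matrix with two planted blocks of near-identical genes plus
# independent noise genes
planted_fc <- function(block_sizes, n_acc, within_noise = 0.1,
                       n_noise = 0L, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (b in seq_along(block_sizes)) {
    pat <- rnorm(n_acc)
    for (g in seq_len(block_sizes[b]))
      rows[[length(rows) + 1L]] <- pat + rnorm(n_acc, 0, within_noise)
  }
  for (g in seq_len(n_noise))
    rows[[length(rows) + 1L]] <- rnorm(n_acc)
  fc <- do.call(rbind, rows)
  dimnames(fc) <- list(paste0("g", seq_len(nrow(fc))),
                       paste0("A", seq_len(n_acc)))
  fc
}

# exactly column-orthonormal centered design with X'X = n I
orthonormal_design <- function(n, P, seed = 1L) {
  set.seed(seed)
  M <- scale(matrix(rnorm(n * P), n, P), scale = FALSE)
  X <- sqrt(n) * qr.Q(qr(M))
  colnames(X) <- paste0("V", seq_len(P))
  rownames(X) <- paste0("S", seq_len(n))
  X
}
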