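#' Filtering and fold-change configuration
#'
#' Defaults follow the pipeline's published settings: genes are dropped when
#' the upper/lower quartile ratio of their normalized counts is below 1.5,
#' or when more than 80% of samples have counts below 10; after fold-change
#' computation, genes with interquartile spread of log2 fold change not
#' exceeding 0.25 are dropped.
#'
#' @param count_qratio_min minimum upper/lower quantile ratio of counts.
#' @param low_count count threshold for the low-expression criterion.
#' @param low_count_frac maximal tolerated fraction of samples below
#'   `low_count`.
#' @param fc_spread_min minimum per-gene spread of log2 fold change.
#' @param pseudocount added to both counts before the ratio, stabilizing
#'   zeros.
#' @param upper_q,lower_q quantile levels (linear-interpolation quantiles).
#' @param spread_mode `"iqr"` tests Q_upper - Q_lower > `fc_spread_min` on
#'   the log2 scale (default); `"ratio"` tests Q_upper / Q_lower, the
#'   literal reading, which is ill-behaved for signed values.
#' @return a `modstick_filter_config` list.
#' @export
filter_config <- function(count_qratio_min = 1.5, low_count = 10,
                          low_count_frac = 0.8, fc_spread_min = 0.25,
                          pseudocount = 1.0, upper_q = 0.75, lower_q = 0.25,
                          spread_mode = c("iqr", "ratio")) {
  stopifnot_scalar_number(count_qratio_min, "count_qratio_min", min = 0)
  stopifnot_scalar_number(low_count, "low_count", min = 0)
  stopifnot_scalar_number(low_count_frac, "low_count_frac", min = 0, max = 1)
  stopifnot_scalar_number(fc_spread_min, "fc_spread_min", min = 0)
  stopifnot_scalar_number(pseudocount, "pseudocount", min = 0)
  stopifnot_scalar_number(lower_q, "lower_q", min = 0, max = 1)
  stopifnot_scalar_number(upper_q, "upper_q", min = 0, max = 1)
  if (!(lower_q < upper_q))
    ms_stop("lower_q must be strictly below upper_q", "modstick_validation_error")
  structure(list(count_qratio_min = count_qratio_min, low_count = low_count,
                 low_count_frac = low_count_frac, fc_spread_min = fc_spread_min,
                 pseudocount = pseudocount, upper_q = upper_q,
                 lower_q = lower_q, spread_mode = match.arg(spread_mode)),
            class = "modstick_filter_config")
}

#' Remove low-information genes
#'
#' Applies two per-gene criteria over all samples (control and stress
#' pooled): (a) ratio of upper to lower count quantile below
#' `count_qratio_min` (a zero lower quantile counts as an infinite ratio,
#' i.e. high dispersion, so the gene is kept by this criterion); (b) more
#' than `low_count_frac` of samples with counts below `low_count`. Genes
#' failing either criterion are removed; gene order is preserved.
#'
#' @param data a `modstick_expression` dataset.
#' @param cfg a [filter_config()].
#' @return the filtered dataset; if every gene is removed, an empty dataset
#'   is returned with a warning. The removal reason per dropped gene is
#'   attached as attribute `"filter_report"`.
#' @export
filter_low_information <- function(data, cfg = filter_config()) {
  counts <- data$counts
  if (nrow(counts) == 0L) {
    attr(data, "filter_report") <- data.frame(gene_id = character(0),
                                              criterion = character(0))
    return(data)
  }
  qs <- t(apply(counts, 1L, stats::quantile,
                probs = c(cfg$lower_q, cfg$upper_q), names = FALSE))
  ratio <- ifelse(qs[, 1L] == 0, Inf, qs[, 2L] / qs[, 1L])
  fail_a <- ratio < cfg$count_qratio_min
  frac_low <- rowMeans(counts < cfg$low_count)
  fail_b <- frac_low > cfg$low_count_frac
  keep <- !fail_a & !fail_b
  report <- data.frame(gene_id = rownames(counts)[!keep],
                       criterion = ifelse(fail_a[!keep], "low_variation",
                                          "low_expression"))
  if (!any(keep))
    ms_warn("all genes removed by low-information filter",
            "modstick_empty_result")
  out <- data
  out$counts <- counts[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Compute the per-accession log2 fold-change matrix
#'
#' For each paired accession, `log2((stress + pseudocount) /
#' (control + pseudocount))`, so that equal counts (including the 0/0 pair)
#' map to 0. Columns are ordered by accession order of first appearance in
#' the sample metadata.
#'
#' @param data a paired `modstick_expression` dataset.
#' @param cfg a [filter_config()] (only `pseudocount` is used).
#' @return genes x accessions numeric matrix of log2 fold changes.
#' @export
compute_log2_foldchange <- function(data, cfg = filter_config()) {
  sm <- data$sample_meta
  acc <- paired_accessions(data)
  orphan <- setdiff(unique(sm$accession), acc)
  if (length(orphan))
    ms_stop(paste0("unpaired accession(s): ", paste(orphan, collapse = ", ")),
            "modstick_validation_error")
  ctrl_ids <- sm$sample_id[match(paste(acc, "control"),
                                 paste(sm$accession, sm$condition))]
  strs_ids <- sm$sample_id[match(paste(acc, "stress"),
                                 paste(sm$accession, sm$condition))]
  fc <- log2((data$counts[, strs_ids, drop = FALSE] + cfg$pseudocount) /
             (data$counts[, ctrl_ids, drop = FALSE] + cfg$pseudocount))
  if (any(!is.finite(fc)))
    ms_stop("non-finite fold change; use a positive pseudocount with zero counts",
            "modstick_validation_error")
  colnames(fc) <- acc
  fc
}

#' Remove genes with flat fold-change profiles
#'
#' Keeps genes whose per-gene spread statistic across accessions exceeds
#' `fc_spread_min`. By default the spread is the interquartile range
#' Q_upper - Q_lower of the log2 values, the reading that behaves sensibly
#' for signed fold changes; a literal quantile-ratio mode is available via
#' `spread_mode = "ratio"` in the config.
#'
#' @param fc genes x accessions log2 fold-change matrix.
#' @param cfg a [filter_config()].
#' @return the filtered matrix (gene order preserved); empty with a warning
#'   if no gene passes.
#' @export
filter_fc_variation <- function(fc, cfg = filter_config()) {
  if (nrow(fc) == 0L) return(fc)
  qs <- t(apply(fc, 1L, stats::quantile,
                probs = c(cfg$lower_q, cfg$upper_q), names = FALSE))
  spread <- if (cfg$spread_mode == "iqr") {
    qs[, 2L] - qs[, 1L]
  } else {
    ifelse(qs[, 1L] == 0, Inf, qs[, 2L] / qs[, 1L])
  }
  # threshold 0 disables the filter entirely (a constant gene has spread 0)
  keep <- if (cfg$fc_spread_min == 0) rep(TRUE, nrow(fc)) else
    spread > cfg$fc_spread_min
  if (!any(keep))
    ms_warn("all genes removed by fold-change variation filter",
            "modstick_empty_result")
  fc[keep, , drop = FALSE]
}
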