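#' Full pipeline configuration
#'
#' Nested configuration for the end-to-end workflow, every default equal to
#' the published analysis settings: count-quantile ratio 1.5, low-count
#' threshold 10 at 80% of samples, fold-change spread 0.25, soft power 4,
#' minimum module size 25, top-3 components per module, 10,000 broken-stick
#' draws at the 95% null quantile, LASSO with leave-one-out CV and the
#' one-standard-error rule.
#'
#' @param filter a [filter_config()].
#' @param network a [network_config()].
#' @param selection a [selection_config()].
#' @param n_pcs components retained per module ("virtual genes").
#' @param stick_n_draws,stick_quantile,stick_rule broken-stick test
#'   settings.
#' @param seed integer seed driving the broken-stick draws (one sub-seed
#'   per tested component).
#' @return a `modstick_pipeline_config` nested list.
#' @export
pipeline_config <- function(filter = filter_config(),
                            network = network_config(),
                            selection = selection_config(),
                            n_pcs = 3L, stick_n_draws = 10000L,
                            stick_quantile = 0.95,
                            stick_rule = c("contiguous", "all"),
                            seed = 1L) {
  structure(list(filter = filter, network = network, selection = selection,
                 n_pcs = as.integer(n_pcs),
                 stick_n_draws = as.integer(stick_n_draws),
                 stick_quantile = stick_quantile,
                 stick_rule = match.arg(stick_rule),
                 seed = as.integer(seed)),
            class = "modstick_pipeline_config")
}

#' Serialize / parse a pipeline configuration (YAML)
#'
#' Round-trip safe: `read_pipeline_config(write_pipeline_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `modstick_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(NULL)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(filter = do.call(filter_config, raw$filter),
                  network = do.call(network_config, raw$network),
                  selection = do.call(selection_config, raw$selection),
                  n_pcs = raw$n_pcs, stick_n_draws = raw$stick_n_draws,
                  stick_quantile = raw$stick_quantile,
                  stick_rule = raw$stick_rule, seed = raw$seed)
}

#' Run the full submodule-discovery pipeline
#'
#' Chains all stages: low-information filter, log2 fold change, fold-change
#' variation filter, adjacency + TOM + module detection (or an imported
#' partition), per-module PCA, penalized selection of phenotype-associated
#' components, and the broken-stick contribution test on every selected
#' component. Gene counts after every stage are logged and collected into
#' a machine-readable run manifest.
#'
#' @param data a `modstick_expression` dataset.
#' @param phenotype named numeric vector (names = accessions).
#' @param config a [pipeline_config()].
#' @param partition optional precomputed named module-label vector,
#'   bypassing network construction.
#' @param out_dir optional directory; when given, every stage's output and
#'   a JSON run manifest are written there.
#' @param quiet suppress progress messages.
#' @return a `modstick_pipeline_result` list: `fc`, `partition`, `decomps`,
#'   `vgm`, `selection`, `stick_tests` (one per selected component),
#'   `significant_genes`, `manifest`.
#' @export
run_pipeline <- function(data, phenotype, config = pipeline_config(),
                         partition = NULL, out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  say("[preprocess] %d genes, %d samples", nrow(data$counts), ncol(data$counts))
  filtered <- filter_low_information(data, config$filter)
  say("[preprocess] %d genes after low-information filter", nrow(filtered$counts))
  fc <- compute_log2_foldchange(filtered, config$filter)
  fc <- filter_fc_variation(fc, config$filter)
  say("[preprocess] %d genes after fold-change variation filter", nrow(fc))

  acc <- colnames(fc)
  if (!setequal(names(phenotype), acc))
    ms_stop("phenotype accessions do not match the paired accessions",
            "modstick_validation_error")
  phenotype <- phenotype[acc]

  if (is.null(partition)) {
    adj <- compute_adjacency(fc, config$network)
    sf <- suppressWarnings(scale_free_fit(adj, config$network))
    tom <- compute_tom(adj)
    partition <- detect_modules(tom, config$network)
    say("[network] scale-free fit R^2 = %.3f; %d modules",
        sf, max(partition))
  } else {
    partition <- partition[intersect(names(partition), rownames(fc))]
    missing <- setdiff(rownames(fc), names(partition))
    if (length(missing)) {
      partition <- c(partition,
                     stats::setNames(integer(length(missing)), missing))
    }
    partition <- partition[rownames(fc)]
    sf <- NA_real_
    say("[network] using imported partition: %d modules", max(partition))
  }
  n_modules <- max(partition)
  if (n_modules == 0L)
    ms_stop("no module passed the minimum size; nothing to decompose",
            "modstick_pipeline_error")

  decomps <- decompose_all_modules(fc, partition, n_pcs = config$n_pcs)
  vgm <- build_virtual_gene_matrix(decomps)
  say("[decompose] %d virtual genes from %d modules", ncol(vgm), n_modules)

  fit <- select_virtual_genes(vgm, phenotype, config$selection)
  say("[select] lambda_chosen = %.5g (%s rule); %d component(s) selected: %s",
      fit$lambda_chosen, config$selection$rule, length(fit$selected),
      if (length(fit$selected)) paste(fit$selected, collapse = ", ") else "-")

  stick_tests <- list()
  nulls_cache <- list()
  for (si in seq_along(fit$selected)) {
    key <- fit$selected[si]
    km <- fit$keys[key, ]
    d <- decomps[[km$module]]
    contrib <- gene_contributions(d, km$pc)
    cache_id <- as.character(length(d$gene_ids))
    if (is.null(nulls_cache[[cache_id]]))
      nulls_cache[[cache_id]] <- broken_stick_null(
        length(d$gene_ids), n_draws = config$stick_n_draws,
        seed = sub_seed(config$seed, length(d$gene_ids)),
        quantile = config$stick_quantile)
    cors <- gene_pc_correlation(fc, d$gene_ids, d$scores[, km$pc])
    res <- test_genes(contrib, nulls_cache[[cache_id]],
                      rule = config$stick_rule, correlations = cors)
    stick_tests[[key]] <- res
    say("[test-genes] %s: %d / %d genes significant", key,
        sum(res$table$significant), res$n_tests)
  }
  significant <- unique(unlist(lapply(stick_tests, function(r)
    r$table$gene_id[r$table$significant])))

  manifest <- list(
    started = t_start,
    seed = config$seed,
    parameters = list(filter = unclass(config$filter),
                      network = unclass(config$network),
                      selection = unclass(config$selection),
                      n_pcs = config$n_pcs,
                      stick = list(n_draws = config$stick_n_draws,
                                   quantile = config$stick_quantile,
                                   rule = config$stick_rule)),
    counts = list(genes_input = nrow(data$counts),
                  genes_after_low_information = nrow(filtered$counts),
                  genes_after_fc_variation = nrow(fc),
                  accessions = length(acc),
                  modules = n_modules,
                  virtual_genes = ncol(vgm),
                  selected_components = length(fit$selected),
                  stick_tests = length(stick_tests),
                  significant_genes = length(significant)),
    scale_free_fit = sf,
    lambda_min = fit$lambda_min,
    lambda_chosen = fit$lambda_chosen,
    selected = as.list(fit$selected))

  result <- structure(list(fc = fc, partition = partition, decomps = decomps,
                           vgm = vgm, selection = fit,
                           stick_tests = stick_tests,
                           significant_genes = significant,
                           manifest = manifest),
                      class = "modstick_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_foldchange_table(fc, file.path(out_dir, "foldchange.tsv"))
    write_module_partition(partition, file.path(out_dir, "partition.tsv"))
    write_results(fit, file.path(out_dir, "selection.tsv"))
    for (key in names(stick_tests))
      write_results(stick_tests[[key]],
                    file.path(out_dir, paste0("stick_", gsub("\\W", "_", key),
                                              ".tsv")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.modstick_pipeline_result <- function(x, ...) {
  cn <- x$manifest$counts
  cat(sprintf(paste0("modstick pipeline: %d -> %d -> %d genes, %d modules, ",
                     "%d virtual genes, %d selected, %d significant genes\n"),
              cn$genes_input, cn$genes_after_low_information,
              cn$genes_after_fc_variation, cn$modules, cn$virtual_genes,
              cn$selected_components, cn$significant_genes))
  invisible(x)
}
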