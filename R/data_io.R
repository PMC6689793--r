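#' Construct a validated expression dataset
#'
#' An expression dataset couples a genes x samples matrix of normalized
#' counts with per-sample metadata describing the paired design: every
#' accession measured under stress must also be measured under control.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param sample_meta data.frame with columns `sample_id`, `accession`,
#'   `condition` (values normalized case-insensitively to `"control"` /
#'   `"stress"`), one row per sample.
#' @return An object of class `modstick_expression`: a list with elements
#'   `counts` and `sample_meta`.
#' @examples
#' counts <- matrix(1:12, 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    accession = rep(c("A1", "A2"), each = 2),
#'                    condition = rep(c("control", "stress"), 2))
#' ds <- expression_dataset(counts, meta)
#' @export
expression_dataset <- function(counts, sample_meta) {
  if (!is.matrix(counts) || !is.numeric(counts))
    ms_stop("'counts' must be a numeric matrix", "modstick_format_error")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    ms_stop("'counts' must carry gene ids as rownames and sample ids as colnames",
            "modstick_format_error")
  if (anyDuplicated(rownames(counts)))
    ms_stop("duplicate gene ids in expression matrix", "modstick_format_error")
  if (anyDuplicated(colnames(counts)))
    ms_stop("duplicate sample ids in expression matrix", "modstick_format_error")
  if (anyNA(counts))
    ms_stop("expression matrix contains missing values", "modstick_validation_error")
  if (any(counts < 0))
    ms_stop("expression matrix contains negative values", "modstick_validation_error")

  required <- c("sample_id", "accession", "condition")
  if (!is.data.frame(sample_meta) || !all(required %in% names(sample_meta)))
    ms_stop("sample_meta must have columns sample_id, accession, condition",
            "modstick_format_error")
  sample_meta <- sample_meta[, required]
  sample_meta[] <- lapply(sample_meta, as.character)
  cond <- tolower(trimws(sample_meta$condition))
  bad <- setdiff(unique(cond), c("control", "stress"))
  if (length(bad))
    ms_stop(paste0("unknown condition value(s): ", paste(bad, collapse = ", "),
                   " (expected control/stress)"), "modstick_format_error")
  sample_meta$condition <- cond
  if (anyDuplicated(sample_meta$sample_id))
    ms_stop("duplicate sample ids in metadata", "modstick_format_error")
  if (!setequal(sample_meta$sample_id, colnames(counts)))
    ms_stop("sample ids in metadata do not match expression matrix columns",
            "modstick_format_error")
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ]
  rownames(sample_meta) <- NULL

  key <- paste(sample_meta$accession, sample_meta$condition)
  if (anyDuplicated(key))
    ms_stop(paste0("accession measured more than once under one condition: ",
                   key[duplicated(key)][1L]), "modstick_validation_error")
  stress_acc <- sample_meta$accession[sample_meta$condition == "stress"]
  control_acc <- sample_meta$accession[sample_meta$condition == "control"]
  unpaired <- setdiff(stress_acc, control_acc)
  if (length(unpaired))
    ms_stop(paste0("stress accession(s) without a control sample: ",
                   paste(unpaired, collapse = ", ")),
            "modstick_validation_error")

  structure(list(counts = counts, sample_meta = sample_meta),
            class = "modstick_expression")
}

#' @export
print.modstick_expression <- function(x, ...) {
  n_acc <- length(unique(x$sample_meta$accession))
  cat(sprintf("modstick expression dataset: %d genes x %d samples (%d accessions)\n",
              nrow(x$counts), ncol(x$counts), n_acc))
  invisible(x)
}

#' @export
dim.modstick_expression <- function(x) dim(x$counts)

#' Accessions with both a control and a stress sample
#' @param data a `modstick_expression` dataset.
#' @return character vector of paired accession ids, in order of first
#'   appearance in the sample metadata.
#' @export
paired_accessions <- function(data) {
  sm <- data$sample_meta
  acc <- unique(sm$accession)
  acc[acc %in% sm$accession[sm$condition == "stress"] &
      acc %in% sm$accession[sm$condition == "control"]]
}

read_numeric_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    ms_stop(sprintf("'%s': expected an id column plus data columns", path),
            "modstick_format_error")
  ids <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    ms_stop(sprintf("'%s': non-numeric value '%s' at row %d, column '%s'",
                    path, vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                    colnames(vals)[bad[1L, 2L]]),
            "modstick_parse_error")
  if (anyNA(num))
    ms_stop(sprintf("'%s': missing values are not allowed", path),
            "modstick_parse_error")
  rownames(num) <- ids
  num
}

#' Read an expression matrix and its sample metadata
#'
#' The expression file is a TSV with a header row of sample ids and gene ids
#' in the first column; the metadata file is a TSV with columns
#' `sample_id`, `accession`, `condition`. Row and column order is preserved.
#'
#' @param path path to the expression TSV.
#' @param meta_path path to the sample metadata TSV.
#' @return a validated [expression_dataset()].
#' @export
read_expression_table <- function(path, meta_path) {
  counts <- read_numeric_tsv(path)
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
  expression_dataset(counts, meta)
}

#' Write an expression dataset to TSV files
#' @param data a `modstick_expression` dataset.
#' @param path output path for the expression TSV.
#' @param meta_path output path for the metadata TSV.
#' @export
write_expression_table <- function(data, path, meta_path) {
  write_tsv_matrix(data$counts, path, id_col = "gene_id")
  utils::write.table(data$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a phenotype table
#'
#' Two-column TSV (`accession`, `value`); the phenotype is expected on a log2
#' scale (e.g. log2 of the shoot Na+/K+ concentration ratio).
#'
#' @param path path to the phenotype TSV.
#' @return named numeric vector of phenotype values, names = accessions, in
#'   file order.
#' @export
read_phenotype_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) != 2L)
    ms_stop(sprintf("'%s': phenotype table must have exactly two columns", path),
            "modstick_format_error")
  if (anyDuplicated(tab[[1L]]))
    ms_stop(sprintf("'%s': duplicated accession '%s'", path,
                    tab[[1L]][duplicated(tab[[1L]])][1L]),
            "modstick_format_error")
  vals <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(vals))
    ms_stop(sprintf("'%s': missing or non-numeric phenotype value for accession '%s'",
                    path, tab[[1L]][which(is.na(vals))[1L]]),
            "modstick_parse_error")
  stats::setNames(vals, tab[[1L]])
}

#' Write a phenotype table
#' @param phenotype named numeric vector (names = accessions).
#' @param path output TSV path.
#' @export
write_phenotype_table <- function(phenotype, path) {
  df <- data.frame(accession = names(phenotype),
                   value = format_num(unname(phenotype)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a gene-to-module partition
#' @param path TSV with columns `gene_id`, `module_label` (0 = unassigned).
#' @return named integer vector of module labels.
#' @export
read_module_partition <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) != 2L)
    ms_stop(sprintf("'%s': partition table must have exactly two columns", path),
            "modstick_format_error")
  if (anyDuplicated(tab[[1L]]))
    ms_stop(sprintf("'%s': duplicated gene id", path), "modstick_format_error")
  lab <- suppressWarnings(as.integer(tab[[2L]]))
  if (anyNA(lab) || any(lab < 0L))
    ms_stop(sprintf("'%s': module labels must be non-negative integers", path),
            "modstick_parse_error")
  stats::setNames(lab, tab[[1L]])
}

#' Write a gene-to-module partition
#' @param partition named integer vector of module labels.
#' @param path output TSV path.
#' @export
write_module_partition <- function(partition, path) {
  df <- data.frame(gene_id = names(partition),
                   module_label = as.integer(partition))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

# Fixed float format so that serialization is deterministic and
# byte-identical across runs; 12 significant digits round-trips doubles
# well inside the 1e-9 contract.
format_num <- function(x) formatC(x, format = "g", digits = 12)

write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), apply(m, 2L, format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write an analysis result to a TSV file
#'
#' Deterministic serialization (fixed column order, fixed float format):
#' writing the same result twice produces byte-identical files, and
#' re-reading reproduces the content to the formatting precision.
#'
#' @param result a `modstick_selection` or `modstick_broken_stick` object.
#' @param path output TSV path.
#' @export
write_results <- function(result, path) UseMethod("write_results")

#' @export
write_results.modstick_selection <- function(result, path) {
  keys <- result$keys
  df <- data.frame(feature = names(result$coefficients),
                   module = keys$module, pc = keys$pc,
                   coefficient = format_num(unname(result$coefficients)),
                   selected = names(result$coefficients) %in% result$selected,
                   rank = match(names(result$coefficients), result$ranking))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @export
write_results.modstick_broken_stick <- function(result, path) {
  tab <- result$table
  df <- data.frame(gene_id = tab$gene_id,
                   module = result$module_id, pc = result$pc_index,
                   contribution = format_num(tab$contribution),
                   rank = tab$rank,
                   threshold = format_num(tab$threshold),
                   significant = tab$significant)
  if (!is.null(tab$correlation)) df$correlation <- format_num(tab$correlation)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write a log2 fold-change matrix
#' @param fc genes x accessions fold-change matrix.
#' @param path output TSV path.
#' @export
write_foldchange_table <- function(fc, path) {
  write_tsv_matrix(fc, path, id_col = "gene_id")
}

#' Read a log2 fold-change matrix written by [write_foldchange_table()]
#' @param path TSV path (gene ids in first column, accessions in header).
#' @return genes x accessions numeric matrix.
#' @export
read_foldchange_table <- function(path) read_numeric_tsv(path)
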