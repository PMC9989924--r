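#' Construct an expression matrix object
#'
#' An `expression_matrix` is the substrate of all correlation work in this
#' package: a numeric genes x samples matrix with unique, ordered gene and
#' sample identifiers, a per-sample condition label and a units flag.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param sample_ids Character vector of unique sample identifiers (columns).
#' @param condition Per-sample labels, each one of `"control"`, `"treated"`,
#'   `"unknown"`. Recycled from a single value.
#' @param units Either `"counts"` (raw, nonnegative) or `"normalized"`.
#' @return An object of class `expression_matrix` with fields `values`,
#'   `gene_ids`, `sample_ids`, `condition`, `units`, `n_samples`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              condition = "unknown",
                              units = c("normalized", "counts")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene_ids and sample_ids are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) stop("gene_ids length != nrow(values)")
  if (length(sample_ids) != ncol(values)) stop("sample_ids length != ncol(values)")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (ncol(values) < 3) {
    stop("at least 3 samples are required (got ", ncol(values), ")")
  }
  condition <- rep_len(as.character(condition), ncol(values))
  bad <- setdiff(unique(condition), c("control", "treated", "unknown"))
  if (length(bad)) stop("invalid condition label(s): ", paste(bad, collapse = ", "))
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         condition = condition, units = units, n_samples = ncol(values)),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", length(x$gene_ids), " genes x ", x$n_samples,
      " samples (", x$units, ")\n", sep = "")
  tab <- table(x$condition)
  cat("conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a gene x sample expression TSV
#'
#' Expects UTF-8 tab-separated text: header row of sample ids (first header
#' cell ignored), one gene per row with the identifier in the first column.
#' Condition labels are taken from an optional sample sheet (TSV with columns
#' `sample_id`, `condition`); samples absent from the sheet are `"unknown"`.
#'
#' @param path Path to the expression TSV.
#' @param sample_sheet Optional path to the sample-sheet TSV.
#' @param transpose If `TRUE` the file stores samples in rows; the matrix is
#'   transposed after reading so genes end up in rows.
#' @param units Units flag recorded on the result (`"normalized"` default).
#' @return An [expression_matrix].
#' @export
load_expression <- function(path, sample_sheet = NULL, transpose = FALSE,
                            units = c("normalized", "counts")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (ncol(raw) < 2) stop("expression TSV needs an id column plus data columns")
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate gene id(s) in ", path, ": ",
                        paste(dup, collapse = ", "))
  num <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(ids, colnames(raw)[-1]))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric value at gene '", ids[idx[1]], "', sample '",
         colnames(num)[idx[2]], "' in ", path)
  }
  if (transpose) num <- t(num)
  condition <- rep("unknown", ncol(num))
  if (!is.null(sample_sheet)) {
    if (!file.exists(sample_sheet)) stop("sample sheet not found: ", sample_sheet)
    sheet <- utils::read.delim(sample_sheet, header = TRUE,
                               colClasses = "character", sep = "\t")
    if (!all(c("sample_id", "condition") %in% colnames(sheet))) {
      stop("sample sheet must have columns sample_id, condition")
    }
    m <- match(colnames(num), sheet$sample_id)
    condition[!is.na(m)] <- sheet$condition[m[!is.na(m)]]
  }
  expression_matrix(num, rownames(num), colnames(num),
                    condition = condition, units = units)
}

#' Write an expression matrix (and optional sample sheet) as TSV
#'
#' Inverse of [load_expression()]: `load(write(x))` round-trips ids and values.
#'
#' @param matrix An [expression_matrix].
#' @param path Output TSV path.
#' @param sample_sheet Optional path for a `sample_id`/`condition` TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path, sample_sheet = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  # %.17g guarantees the decimal text reads back to the identical double
  chr <- apply(matrix$values, 2, function(col) sprintf("%.17g", col))
  df <- data.frame(gene_id = matrix$gene_ids, chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", matrix$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet)) {
    utils::write.table(
      data.frame(sample_id = matrix$sample_ids, condition = matrix$condition),
      sample_sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Log-transform expression values
#'
#' Replaces every value x by `log2(x + pseudocount)`. Intended for raw counts;
#' matrices already flagged `"normalized"` are typically left alone (the
#' pipeline applies this only when `units == "counts"`).
#'
#' @param matrix An [expression_matrix] with nonnegative values.
#' @param pseudocount Positive offset added before the log (default 1).
#' @return The transformed [expression_matrix], flagged `"normalized"`.
#' @export
normalize_log <- function(matrix, pseudocount = 1) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("pseudocount must be a single positive number")
  }
  if (any(matrix$values < 0)) stop("normalize_log requires nonnegative values")
  expression_matrix(log2(matrix$values + pseudocount),
                    matrix$gene_ids, matrix$sample_ids,
                    condition = matrix$condition, units = "normalized")
}

#' Drop genes with zero variance across samples
#'
#' Zero-variance genes make Pearson correlation undefined and must be removed
#' before any profile computation. Idempotent.
#'
#' @param matrix An [expression_matrix].
#' @return A list with `matrix` (the filtered [expression_matrix]) and
#'   `removed` (character vector of dropped gene ids, possibly empty).
#' @export
filter_invariant_genes <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  v <- apply(matrix$values, 1, stats::var)
  keep <- v > 0
  if (!any(keep)) stop("all genes have zero variance; nothing left to analyze")
  removed <- matrix$gene_ids[!keep]
  if (length(removed)) {
    message("filter_invariant_genes: removed ", length(removed),
            " zero-variance gene(s)")
  }
  out <- expression_matrix(matrix$values[keep, , drop = FALSE],
                           matrix$gene_ids[keep], matrix$sample_ids,
                           condition = matrix$condition, units = matrix$units)
  list(matrix = out, removed = removed)
}

#' Restrict an expression matrix to one condition
#'
#' @param matrix An [expression_matrix].
#' @param condition `"control"` or `"treated"`.
#' @return An [expression_matrix] containing only matching samples.
#' @export
stratify_condition <- function(matrix, condition = c("control", "treated")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  condition <- match.arg(condition)
  keep <- matrix$condition == condition
  if (sum(keep) < 3) {
    stop("fewer than 3 samples with condition '", condition, "'")
  }
  expression_matrix(matrix$values[, keep, drop = FALSE], matrix$gene_ids,
                    matrix$sample_ids[keep],
                    condition = matrix$condition[keep], units = matrix$units)
}
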