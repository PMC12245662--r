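#' Construct an expression dataset
#'
#' The benchmark substrate: a samples-by-features numeric matrix with a
#' binary class label per sample and, for matched case/control designs, an
#' optional pair identifier linking each case to its control. The object is
#' validated lazily by [validate_dataset()]; construction only enforces
#' basic shape so that defect-injection tests can build broken datasets.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param labels character/factor vector of per-sample class labels
#'   (exactly two levels expected for a valid dataset).
#' @param positive_class the label treated as "positive" when computing AUC.
#'   Defaults to the second sorted level.
#' @param sample_ids,feature_ids identifier vectors; default to the
#'   dimnames of `values`.
#' @param pair_ids optional per-sample pair identifiers; each id must occur
#'   exactly twice, once per class, for the dataset to validate.
#' @param rpkm_like if `TRUE` the values are declared non-negative
#'   expression units and validation enforces non-negativity.
#' @return an object of class `ExpressionDataset`.
#' @seealso [validate_dataset()], [read_expression_dataset()]
#' @export
expression_dataset <- function(values, labels, positive_class = NULL,
                               sample_ids = rownames(values),
                               feature_ids = colnames(values),
                               pair_ids = NULL, rpkm_like = TRUE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  labels <- as.character(labels)
  if (length(labels) != nrow(values)) {
    stop("`labels` must have one entry per sample (row)")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  rownames(values) <- sample_ids
  colnames(values) <- feature_ids
  if (is.null(positive_class)) positive_class <- sort(unique(labels))[
    min(2L, length(unique(labels)))]
  if (!is.null(pair_ids) && length(pair_ids) != nrow(values)) {
    stop("`pair_ids` must have one entry per sample")
  }
  structure(
    list(values = values, labels = labels,
         positive_class = positive_class,
         sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids),
         pair_ids = if (is.null(pair_ids)) NULL else as.character(pair_ids),
         rpkm_like = isTRUE(rpkm_like)),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$labels)
  cat("  classes: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "),
      sprintf("; positive = %s\n", x$positive_class), sep = "")
  if (!is.null(x$pair_ids)) {
    cat(sprintf("  paired design: %d pair ids\n",
                length(unique(x$pair_ids))))
  }
  invisible(x)
}

#' Number of samples / features in a dataset
#' @param dataset an `ExpressionDataset`.
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$values)

#' @rdname n_samples
#' @export
n_features <- function(dataset) ncol(dataset$values)

#' Validate an expression dataset
#'
#' Checks every dataset invariant and reports violations instead of
#' throwing: all values finite; exactly two label levels; unique sample and
#' feature identifiers; non-negative values when the dataset is declared
#' RPKM-like; and, for paired designs, every pair id occurring exactly
#' twice, once in each class.
#'
#' @param dataset an `ExpressionDataset`.
#' @return character vector of violation descriptions; empty when the
#'   dataset is valid.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  v <- character(0)
  bad <- which(!is.finite(dataset$values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(bad, 1L, function(idx) {
      sprintf("[%s, %s]", dataset$sample_ids[idx[1]],
              dataset$feature_ids[idx[2]])
    })
    v <- c(v, sprintf("non-finite values at %s",
                      paste(utils::head(cells, 5L), collapse = ", ")))
  }
  if (dataset$rpkm_like && nrow(bad) == 0 && any(dataset$values < 0)) {
    v <- c(v, "negative values in an rpkm_like dataset")
  }
  lv <- unique(dataset$labels)
  if (length(lv) != 2L) {
    v <- c(v, sprintf("labels must take exactly two levels, found %d (%s)",
                      length(lv), paste(lv, collapse = ", ")))
  }
  if (!dataset$positive_class %in% lv) {
    v <- c(v, sprintf("positive_class '%s' is not a label level",
                      dataset$positive_class))
  }
  if (anyDuplicated(dataset$sample_ids)) {
    dup <- unique(dataset$sample_ids[duplicated(dataset$sample_ids)])
    v <- c(v, sprintf("duplicated sample ids: %s",
                      paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(dataset$feature_ids)) {
    dup <- unique(dataset$feature_ids[duplicated(dataset$feature_ids)])
    v <- c(v, sprintf("duplicated feature ids: %s",
                      paste(dup, collapse = ", ")))
  }
  if (!is.null(dataset$pair_ids)) {
    counts <- table(dataset$pair_ids)
    bad_n <- names(counts)[counts != 2L]
    if (length(bad_n) > 0) {
      v <- c(v, sprintf("pair ids not occurring exactly twice: %s",
                        paste(bad_n, collapse = ", ")))
    }
    if (length(lv) == 2L) {
      cross <- table(dataset$pair_ids, dataset$labels)
      straddle <- rownames(cross)[apply(cross, 1L, function(r) any(r != 1L))]
      straddle <- setdiff(straddle, bad_n)
      if (length(straddle) > 0) {
        v <- c(v, sprintf("pair ids not split one-per-class: %s",
                          paste(straddle, collapse = ", ")))
      }
    }
  }
  v
}

#' Restrict a dataset to a subset of features or samples
#'
#' @param dataset an `ExpressionDataset`.
#' @param features feature ids to keep (order preserved as given).
#' @param samples sample indices or ids to keep.
#' @return a new `ExpressionDataset`.
#' @export
subset_dataset <- function(dataset, features = NULL, samples = NULL) {
  values <- dataset$values
  labels <- dataset$labels
  pair_ids <- dataset$pair_ids
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, dataset$sample_ids)
    values <- values[samples, , drop = FALSE]
    labels <- labels[samples]
    if (!is.null(pair_ids)) pair_ids <- pair_ids[samples]
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(values))
    if (length(missing) > 0) {
      stop(sprintf("unknown features: %s", paste(missing, collapse = ", ")))
    }
    values <- values[, features, drop = FALSE]
  }
  expression_dataset(values, labels, positive_class = dataset$positive_class,
                     pair_ids = pair_ids, rpkm_like = dataset$rpkm_like)
}

#' Write / read an expression dataset as delimited text
#'
#' The matrix file has a header row of feature ids and a first column of
#' sample ids (samples in rows). Labels, the declared positive class, and
#' optional pair ids are written to a companion two/three-column file.
#' `read_expression_dataset()` auto-detects a genes-in-rows matrix (feature
#' ids in the first column instead of sample ids) by matching the first
#' column against the label file's sample ids and transposes it.
#'
#' @param dataset an `ExpressionDataset`.
#' @param matrix_file path for the expression matrix.
#' @param labels_file path for the sample annotation table.
#' @param sep field delimiter, tab by default.
#' @return `write_expression_dataset()` returns the dataset invisibly;
#'   `read_expression_dataset()` returns an `ExpressionDataset`.
#' @export
write_expression_dataset <- function(dataset, matrix_file, labels_file,
                                     sep = "\t") {
  df <- data.frame(sample_id = dataset$sample_ids,
                   dataset$values, check.names = FALSE)
  utils::write.table(df, matrix_file, sep = sep, row.names = FALSE,
                     quote = FALSE)
  ann <- data.frame(sample_id = dataset$sample_ids, label = dataset$labels)
  if (!is.null(dataset$pair_ids)) ann$pair_id <- dataset$pair_ids
  attr_line <- sprintf("#positive_class=%s", dataset$positive_class)
  con <- file(labels_file, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(ann, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(dataset)
}

#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(matrix_file, labels_file, sep = "\t") {
  lines <- readLines(labels_file)
  positive <- NULL
  hdr <- grep("^#positive_class=", lines)
  if (length(hdr) > 0) {
    positive <- sub("^#positive_class=", "", lines[hdr[1]])
  }
  ann <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           sep = sep, header = TRUE,
                           colClasses = "character")
  mat <- utils::read.table(matrix_file, sep = sep, header = TRUE,
                           check.names = FALSE)
  first_col <- as.character(mat[[1]])
  if (!any(first_col %in% ann$sample_id) &&
      any(colnames(mat)[-1] %in% ann$sample_id)) {
    # genes-in-rows orientation: transpose
    values <- t(as.matrix(mat[, -1, drop = FALSE]))
    colnames(values) <- first_col
  } else {
    values <- as.matrix(mat[, -1, drop = FALSE])
    rownames(values) <- first_col
  }
  idx <- match(rownames(values), ann$sample_id)
  if (anyNA(idx)) {
    stop("samples in the matrix file are missing from the labels file")
  }
  expression_dataset(values,
                     labels = ann$label[idx],
                     positive_class = positive,
                     sample_ids = rownames(values),
                     pair_ids = if ("pair_id" %in% names(ann))
                       ann$pair_id[idx] else NULL)
}
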