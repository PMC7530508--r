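#' Write a feature matrix as TSV
#'
#' First column `id`, then one named column per feature (e.g. `DC_AC`,
#' `CTF_1_2_2`, `PseACS_C13a_lag3`); optionally a `label` column.
#'
#' @param X Feature matrix with rownames and colnames.
#' @param path Output path.
#' @param labels Optional label vector (one per row).
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path, labels = NULL) {
  df <- data.frame(id = rownames(X) %||% paste0("row", seq_len(nrow(X))),
                   as.data.frame(X, optional = TRUE), check.names = FALSE)
  if (!is.null(labels)) df$label <- as.character(labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path Path to the TSV.
#' @return List with `X` (numeric matrix, rownames from the `id` column)
#'   and `labels` (character vector or `NULL`).
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("feature TSV needs an 'id' column",
                                 call. = FALSE)
  labels <- if ("label" %in% names(df)) df$label else NULL
  feat <- setdiff(names(df), c("id", "label"))
  X <- as.matrix(df[feat])
  storage.mode(X) <- "double"
  rownames(X) <- df$id
  list(X = X, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
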