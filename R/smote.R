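#' SMOTE configuration
#'
#' @param k_neighbors Number of in-class nearest neighbours considered when
#'   interpolating (default 5, the common default of the original
#'   algorithm's reference implementations). For a class with `n` samples
#'   the effective k is `min(k_neighbors, n - 1)`.
#' @param seed Integer seed making oversampling deterministic.
#' @return List of class `"smote_config"`.
#' @export
smote_config <- function(k_neighbors = 5L, seed = 1L) {
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1", call. = FALSE)
  structure(list(k_neighbors = k_neighbors, seed = as.integer(seed)),
            class = "smote_config")
}

#' Generate synthetic samples for one class by SMOTE interpolation
#'
#' Each synthetic row is `x + u * (x_nn - x)`, where `x` is a class sample,
#' `x_nn` one of its k nearest in-class neighbours (Euclidean distance on
#' the raw feature vectors) and `u` uniform on `[0, 1]` — a point on the
#' line segment joining the two. Base samples are cycled in row order, one
#' synthetic point per pass; the remainder of `n_new` modulo the class size
#' is assigned to a seeded random subset of rows.
#'
#' @param X Numeric matrix of the class's samples (rows).
#' @param n_new Number of synthetic rows to generate.
#' @param cfg A [smote_config()].
#' @return Numeric matrix with `n_new` rows (0-row matrix when
#'   `n_new = 0`).
#' @export
smote_class <- function(X, n_new, cfg = smote_config()) {
  X <- as.matrix(X)
  n_new <- as.integer(n_new)
  if (n_new < 0L) stop("n_new must be >= 0", call. = FALSE)
  if (n_new == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = ncol(X),
                  dimnames = list(NULL, colnames(X))))
  n <- nrow(X)
  if (n < 2L)
    stop("SMOTE needs at least 2 samples in the class (got ", n,
         "): no line segments exist", call. = FALSE)
  k <- min(cfg$k_neighbors, n - 1L)
  d2 <- as.matrix(stats::dist(X))^2
  diag(d2) <- Inf
  # k nearest in-class neighbours per row, nearest first (ties by row index)
  ord <- apply(d2, 1L, function(row) order(row)[seq_len(k)])
  nn <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
  with_seed(cfg$seed, {
    passes <- n_new %/% n
    rem <- n_new %% n
    base <- c(rep(seq_len(n), times = passes),
              if (rem > 0L) sample(seq_len(n), rem))
    pick <- if (k == 1L) rep(1L, n_new) else sample(seq_len(k), n_new,
                                                    replace = TRUE)
    u <- stats::runif(n_new)
    Xb <- X[base, , drop = FALSE]
    Xn <- X[nn[cbind(base, pick)], , drop = FALSE]
    out <- Xb + u * (Xn - Xb)
    rownames(out) <- NULL
    out
  })
}

#' Balance a labeled feature matrix up to the majority class by SMOTE
#'
#' Minority classes are processed smallest-first and each is augmented with
#' synthetic interpolated samples until its count equals the majority
#' count; the majority class and all original rows are preserved verbatim.
#'
#' @param X Numeric feature matrix, one row per sample.
#' @param y Factor (or character) of class labels, one per row.
#' @param cfg A [smote_config()].
#' @return List of class `"balanced_dataset"` with elements `X` (original
#'   rows first, synthetic rows appended), `y`, and `synthetic` (logical
#'   flag per row marking interpolated samples).
#' @export
balance_to_majority <- function(X, y, cfg = smote_config()) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nrow(X) != length(y)) stop("X and y lengths differ", call. = FALSE)
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least 2 classes", call. = FALSE)
  target <- max(counts)
  deficit <- target - counts
  small <- counts[counts < target]
  if (any(counts[names(deficit)[deficit > 0]] < 2L))
    stop("class(es) with fewer than 2 samples cannot be oversampled: ",
         paste(names(counts)[counts < 2L & deficit > 0], collapse = ", "),
         call. = FALSE)
  # smallest class first; ties broken by label order for determinism
  order_classes <- names(sort(small))
  Xs_all <- list()
  ys_all <- character(0)
  for (j in seq_along(order_classes)) {
    cl <- order_classes[j]
    rows <- which(y == cl)
    # distinct per-class seed keeps classes independent yet reproducible
    cl_cfg <- smote_config(cfg$k_neighbors,
                           seed = (cfg$seed + 7919L * j) %% .Machine$integer.max)
    Xs <- tryCatch(smote_class(X[rows, , drop = FALSE],
                               n_new = target - length(rows), cfg = cl_cfg),
                   error = function(e)
                     stop("class '", cl, "': ", conditionMessage(e),
                          call. = FALSE))
    Xs_all[[j]] <- Xs
    ys_all <- c(ys_all, rep(cl, nrow(Xs)))
  }
  Xs_all <- do.call(rbind, Xs_all)
  if (is.null(Xs_all))
    Xs_all <- matrix(numeric(0), 0L, ncol(X), dimnames = list(NULL, colnames(X)))
  out_X <- rbind(X, Xs_all)
  orig_ids <- rownames(X) %||% paste0("row", seq_len(nrow(X)))
  rownames(out_X) <- c(orig_ids,
                       if (nrow(Xs_all) > 0L)
                         paste0("synthetic_", seq_len(nrow(Xs_all))))
  structure(list(X = out_X,
                 y = factor(c(as.character(y), ys_all), levels = levels(y)),
                 synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(Xs_all)))),
            class = "balanced_dataset")
}

#' @export
print.balanced_dataset <- function(x, ...) {
  cat("balanced_dataset:", nrow(x$X), "samples (",
      sum(!x$synthetic), "original +", sum(x$synthetic), "synthetic )\n")
  print(table(x$y))
  invisible(x)
}
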