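#' SVM model configuration
#'
#' Settings for the one-versus-one RBF-kernel SVM and its (cost, gamma)
#' grid search. The default grids are the canonical libsvm practitioner
#' grid: cost over `2^-5 .. 2^15` and gamma over `2^-15 .. 2^3`, both in
#' multiplicative steps of 4. Feature scaling defaults to min-max to
#' `[0, 1]` fitted on the training data (frequency features already live in
#' `[0, 1]`, but PseACS magnitudes do not); `"none"` disables it.
#'
#' @param c_grid Positive reals: candidate soft-margin costs.
#' @param gamma_grid Positive reals: candidate RBF widths.
#' @param scaling `"minmax"` or `"none"`.
#' @param inner_cv_folds Stratified folds for grid-search model selection
#'   (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return List of class `"model_config"`.
#' @export
model_config <- function(c_grid = 2^seq(-5, 15, 2),
                         gamma_grid = 2^seq(-15, 3, 2),
                         scaling = c("minmax", "none"),
                         inner_cv_folds = 5L, seed = 1L) {
  scaling <- match.arg(scaling)
  if (length(c_grid) == 0L || length(gamma_grid) == 0L)
    stop("grids must be non-empty", call. = FALSE)
  if (any(c_grid <= 0) || any(gamma_grid <= 0))
    stop("cost and gamma must be positive", call. = FALSE)
  inner_cv_folds <- as.integer(inner_cv_folds)
  if (inner_cv_folds < 2L) stop("inner_cv_folds must be >= 2", call. = FALSE)
  structure(list(c_grid = sort(unique(c_grid)),
                 gamma_grid = sort(unique(gamma_grid)),
                 kernel = "radial", multiclass = "ovo",
                 scaling = scaling, inner_cv_folds = inner_cv_folds,
                 seed = as.integer(seed)),
            class = "model_config")
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      rows <- which(y == cl)
      folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  folds
}

fit_minmax <- function(X, scaling) {
  if (scaling == "none")
    return(list(type = "none"))
  mins <- apply(X, 2L, min)
  rng <- apply(X, 2L, max) - mins
  rng[rng == 0] <- 1  # constant columns map to 0
  list(type = "minmax", min = mins, range = rng)
}

apply_minmax <- function(X, sc) {
  if (sc$type == "none") return(X)
  sweep(sweep(X, 2L, sc$min, "-"), 2L, sc$range, "/")
}

fit_svm_raw <- function(Xs, y, cost, gamma) {
  # rows sorted by label so libsvm's internal class order (order of first
  # appearance) is the alphabetical level order; this fixes OVO vote
  # tie-breaking deterministically
  o <- order(y)
  e1071::svm(Xs[o, , drop = FALSE], y[o], type = "C-classification",
             kernel = "radial", cost = cost, gamma = gamma, scale = FALSE)
}

#' Train a one-versus-one RBF-kernel SVM with grid search
#'
#' Selects (cost, gamma) by maximising stratified inner-CV overall accuracy
#' over the configured grid (ties broken towards the smallest cost, then
#' the smallest gamma), then refits on the full training data at the
#' winning pair. With a 1 x 1 grid the search is skipped. Scaling
#' statistics are fitted on the training data only. The fitted machine is
#' libsvm's native one-versus-one decomposition: `k (k - 1) / 2` pairwise
#' classifiers combined by majority vote.
#'
#' @param X Numeric feature matrix (rows = samples).
#' @param y Class labels (factor or character).
#' @param cfg A [model_config()].
#' @return Object of class `"hsp_model"`: the fitted svm, the selected
#'   `cost` and `gamma`, scaling parameters, `label_set`, the CV grid table
#'   (`cv`), and training metadata (`n`, `p`).
#' @export
hsp_train <- function(X, y, cfg = model_config()) {
  X <- as.matrix(X)
  y <- factor(y)
  y <- factor(y, levels = sort(levels(y)))
  if (nrow(X) != length(y)) stop("X and y lengths differ", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  sc <- fit_minmax(X, cfg$scaling)
  Xs <- apply_minmax(X, sc)
  grid <- expand.grid(gamma = cfg$gamma_grid, cost = cfg$c_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$cost, grid$gamma), c("cost", "gamma")]
  cv <- NULL
  if (nrow(grid) > 1L) {
    small <- table(y)[table(y) < cfg$inner_cv_folds]
    if (length(small) > 0L)
      stop("class(es) with fewer than inner_cv_folds = ", cfg$inner_cv_folds,
           " samples: ", paste(names(small), collapse = ", "), call. = FALSE)
    folds <- stratified_folds(y, cfg$inner_cv_folds, cfg$seed)
    score <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(cfg$inner_cv_folds)) {
        tr <- folds != f
        fit <- fit_svm_raw(Xs[tr, , drop = FALSE], y[tr],
                           grid$cost[g], grid$gamma[g])
        pred <- predict(fit, Xs[!tr, , drop = FALSE])
        correct <- correct + sum(pred == y[!tr])
      }
      score[g] <- correct / length(y)
    }
    cv <- cbind(grid, accuracy = score)
    best <- which.max(score)  # grid is cost-then-gamma ordered: first max
  } else {
    best <- 1L
  }
  cost <- grid$cost[best]
  gamma <- grid$gamma[best]
  fit <- fit_svm_raw(Xs, y, cost, gamma)
  structure(list(schema_version = 1L, svm = fit, cost = cost, gamma = gamma,
                 scaling = sc, label_set = levels(y), cv = cv, cfg = cfg,
                 n = nrow(X), p = ncol(X),
                 feature_names = colnames(X)),
            class = "hsp_model")
}

#' Predict family labels with a trained SVM
#'
#' Applies the training-fitted scaling, then the one-versus-one majority
#' vote of the fitted pairwise classifiers.
#'
#' @param object An [hsp_train()] model.
#' @param newdata Numeric feature matrix with the training feature
#'   dimension.
#' @param ... Unused.
#' @return Factor of predicted labels (levels = the model's `label_set`);
#'   empty input gives an empty factor.
#' @export
predict.hsp_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("feature dimension mismatch: model has ", object$p,
         ", input has ", ncol(newdata), call. = FALSE)
  if (nrow(newdata) == 0L)
    return(factor(character(0), levels = object$label_set))
  Xs <- apply_minmax(newdata, object$scaling)
  pred <- predict(object$svm, Xs)
  factor(as.character(pred), levels = object$label_set)
}

#' @export
print.hsp_model <- function(x, ...) {
  k <- length(x$label_set)
  cat("hsp_model: OVO RBF-SVM,", k, "classes (",
      k * (k - 1) / 2, "pairwise machines ), cost =", format(x$cost),
      ", gamma =", format(x$gamma), "\n")
  cat("trained on", x$n, "samples x", x$p, "features; scaling:",
      x$scaling$type, "\n")
  invisible(x)
}

#' Save a trained model to a versioned archive
#'
#' The archive is a single RDS file holding a self-describing list
#' (`schema_version`, configuration, scaling parameters, label set, fitted
#' machinery), readable back with [load_model()].
#'
#' @param model An `"hsp_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "hsp_model")) stop("not an hsp_model", call. = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' Load a trained model saved with [save_model()]
#'
#' @param path Path to the model archive.
#' @return An `"hsp_model"`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hsp_model") || is.null(model$schema_version))
    stop("not a recognised hsp_model archive: ", path, call. = FALSE)
  model
}
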