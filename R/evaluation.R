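#' Per-class metrics from one-vs-rest counts
#'
#' Computes sensitivity `Sn = TP / (TP + FN)`, specificity
#' `Sp = TN / (TN + FP)`, Matthews correlation coefficient
#' `MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP))` and
#' accuracy `Acc = (TP + TN) / (TP + TN + FP + FN)`. When any factor of the
#' MCC denominator is zero the MCC is defined as 0 and flagged
#' (`mcc_zero_denominator`), the standard convention for the degenerate
#' case.
#'
#' @param tp,tn,fp,fn Non-negative one-vs-rest counts for one class.
#' @return Named list: `Sn`, `Sp`, `MCC`, `Acc`, `mcc_zero_denominator`.
#' @export
class_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / sum(counts)
  den <- sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tp + fn) * sqrt(tn + fp)
  zero_den <- den == 0
  mcc <- if (zero_den) 0 else (tp * tn - fp * fn) / den
  list(Sn = sn, Sp = sp, MCC = mcc, Acc = acc,
       mcc_zero_denominator = zero_den)
}

#' Confusion matrix and one-vs-rest counts from predictions
#'
#' @param y_true,y_pred Equal-length label vectors, values in `label_set`.
#' @param label_set Character vector of all classes (fixes row/column
#'   order).
#' @return List with `confusion` (rows = true class, columns = predicted)
#'   and `counts`, a data frame of per-class one-vs-rest TP/TN/FP/FN.
#' @export
confusion_from_predictions <- function(y_true, y_pred, label_set) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ", call. = FALSE)
  y_true <- factor(as.character(y_true), levels = label_set)
  y_pred <- factor(as.character(y_pred), levels = label_set)
  if (anyNA(y_true) || anyNA(y_pred))
    stop("labels outside label_set", call. = FALSE)
  cm <- table(true = y_true, predicted = y_pred)
  n <- length(y_true)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  list(confusion = cm,
       counts = data.frame(class = label_set, TP = as.integer(tp),
                           TN = as.integer(tn), FP = as.integer(fp),
                           FN = as.integer(fn), row.names = NULL,
                           stringsAsFactors = FALSE))
}

# assemble the full evaluation report from true/predicted labels
evaluation_report <- function(y_true, y_pred, label_set,
                              protocol = list()) {
  conf <- confusion_from_predictions(y_true, y_pred, label_set)
  per_class <- conf$counts
  metrics <- lapply(seq_len(nrow(per_class)), function(i)
    class_metrics(per_class$TP[i], per_class$TN[i],
                  per_class$FP[i], per_class$FN[i]))
  per_class$Sn <- vapply(metrics, `[[`, numeric(1), "Sn")
  per_class$Sp <- vapply(metrics, `[[`, numeric(1), "Sp")
  per_class$MCC <- vapply(metrics, `[[`, numeric(1), "MCC")
  per_class$Acc <- vapply(metrics, `[[`, numeric(1), "Acc")
  per_class$mcc_zero_denominator <-
    vapply(metrics, `[[`, logical(1), "mcc_zero_denominator")
  n <- length(y_true)
  structure(list(per_class = per_class, confusion = conf$confusion,
                 OA = sum(per_class$TP) / n, N = n, label_set = label_set,
                 protocol = protocol),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  cat("evaluation_report (", x$N, " samples, ",
      length(x$label_set), " classes)\n", sep = "")
  if (length(x$protocol) > 0)
    cat("protocol:", paste(names(x$protocol),
                           vapply(x$protocol, function(v)
                             paste(format(unlist(v)), collapse = "/"), ""),
                           sep = "=", collapse = ", "), "\n")
  tab <- data.frame(class = x$per_class$class,
                    `Sn%` = round(100 * x$per_class$Sn, digits),
                    `Sp%` = round(100 * x$per_class$Sp, digits),
                    MCC = round(x$per_class$MCC, digits),
                    `Acc%` = round(100 * x$per_class$Acc, digits),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat(sprintf("OA%% = %.*f\n", digits, 100 * x$OA))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An evaluation report.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(package_version = as.character(utils::packageVersion("hspfam")),
              protocol = report$protocol,
              N = report$N, OA = report$OA,
              per_class = report$per_class,
              confusion = as.data.frame.matrix(unclass(report$confusion)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# train/predict pair used by the evaluation protocols; `classifier` may be
# "svm" or "majority" (a dummy predicting the most frequent training label,
# ties towards the first level — used as an analytic baseline in tests)
fit_and_predict <- function(Xtr, ytr, Xte, model_cfg, classifier) {
  if (classifier == "majority") {
    tab <- table(ytr)
    lab <- names(tab)[which.max(tab)]
    return(factor(rep(lab, nrow(Xte)), levels = levels(ytr)))
  }
  model <- hsp_train(Xtr, ytr, model_cfg)
  predict(model, Xte)
}

#' Jackknife (leave-one-out) evaluation of the HSP pipeline
#'
#' Runs leave-one-out cross-validation with the grid-searched OVO RBF-SVM
#' and the Sn/Sp/MCC/Acc/OA metric suite. Two protocols are available:
#'
#' * `"as-paper"`: when a `smote_cfg` is given, SMOTE balances the full
#'   dataset once up front and the leave-one-out loop then runs over all
#'   (real + synthetic) samples. This mirrors the usual
#'   balance-then-validate practice but lets synthetic test points be
#'   interpolations of training points, which inflates accuracy.
#' * `"leakage-safe"`: only real samples are ever held out; for each fold
#'   SMOTE is re-applied to the remaining data only.
#'
#' The (cost, gamma) pair is tuned once on the full (balanced) dataset and
#' then held fixed across folds. In as-paper mode the min-max scaling is
#' likewise fitted once up front (consistent with tuning once), which makes
#' the per-fold solution identical to the full-data solution whenever the
#' held-out sample is not a support vector of any pairwise machine — those
#' folds are therefore not retrained (an exact leave-one-out shortcut). In
#' leakage-safe mode scaling and SMOTE are refitted inside every fold.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels.
#' @param model_cfg A [model_config()].
#' @param smote_cfg A [smote_config()], or `NULL` to skip balancing.
#' @param protocol `"as-paper"` or `"leakage-safe"`.
#' @param classifier `"svm"`, or `"majority"` for a dummy
#'   most-frequent-label baseline.
#' @return An `"evaluation_report"` whose `protocol` field records the
#'   protocol, SMOTE placement, tuned parameters and seeds.
#' @export
jackknife <- function(X, y, model_cfg = model_config(), smote_cfg = NULL,
                      protocol = c("as-paper", "leakage-safe"),
                      classifier = c("svm", "majority")) {
  protocol <- match.arg(protocol)
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  y <- factor(y)
  y <- factor(y, levels = sort(levels(y)))
  if (nrow(X) != length(y)) stop("X and y lengths differ", call. = FALSE)
  meta <- list(protocol = "jackknife", smote_placement = protocol,
               smote = !is.null(smote_cfg), classifier = classifier)
  if (protocol == "as-paper") {
    if (!is.null(smote_cfg)) {
      bal <- balance_to_majority(X, y, smote_cfg)
      X <- bal$X
      y <- bal$y
      meta$smote_k <- smote_cfg$k_neighbors
      meta$smote_seed <- smote_cfg$seed
    }
    if (classifier == "majority") {
      pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
      for (i in seq_len(nrow(X))) {
        tab <- table(y[-i])
        pred[i] <- names(tab)[which.max(tab)]
      }
    } else {
      # in as-paper mode scaling and (cost, gamma) are fitted once on the
      # balanced dataset and held fixed across folds; with the solution
      # fixed, removing a non-support-vector of the full model leaves every
      # pairwise machine unchanged, so only support-vector folds are
      # retrained (an exact leave-one-out shortcut)
      tuned_cfg <- tune_once(X, y, model_cfg, classifier)
      cost <- tuned_cfg$c_grid
      gamma <- tuned_cfg$gamma_grid
      meta$cost <- cost
      meta$gamma <- gamma
      o <- order(y)  # label-sorted rows fix libsvm's internal class order
      X <- X[o, , drop = FALSE]
      y <- y[o]
      sc <- fit_minmax(X, model_cfg$scaling)
      Xs <- apply_minmax(X, sc)
      full <- e1071::svm(Xs, y, type = "C-classification",
                         kernel = "radial", cost = cost, gamma = gamma,
                         scale = FALSE)
      pred <- factor(as.character(predict(full, Xs)), levels = levels(y))
      sv_rows <- full$index
      meta$loo_refits <- length(sv_rows)
      for (i in sv_rows) {
        pred[i] <- tryCatch({
          fit <- e1071::svm(Xs[-i, , drop = FALSE], y[-i],
                            type = "C-classification", kernel = "radial",
                            cost = cost, gamma = gamma, scale = FALSE)
          factor(as.character(predict(fit, Xs[i, , drop = FALSE])),
                 levels = levels(y))
        }, error = function(e) stop("jackknife fold ", i, ": ",
                                    conditionMessage(e), call. = FALSE))
      }
    }
  } else {
    tuned_cfg <- model_cfg
    if (!is.null(smote_cfg)) {
      meta$smote_k <- smote_cfg$k_neighbors
      meta$smote_seed <- smote_cfg$seed
    }
    bal0 <- if (!is.null(smote_cfg)) balance_to_majority(X, y, smote_cfg)
            else list(X = X, y = y)
    tuned_cfg <- tune_once(bal0$X, bal0$y, model_cfg, classifier)
    meta$cost <- tuned_cfg$c_grid
    meta$gamma <- tuned_cfg$gamma_grid
    pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
    for (i in seq_len(nrow(X))) {
      Xtr <- X[-i, , drop = FALSE]
      ytr <- y[-i]
      if (!is.null(smote_cfg)) {
        bal <- tryCatch(balance_to_majority(Xtr, ytr, smote_cfg),
                        error = function(e)
                          stop("jackknife fold ", i, ": ",
                               conditionMessage(e), call. = FALSE))
        Xtr <- bal$X
        ytr <- bal$y
      }
      pred[i] <- tryCatch(
        fit_and_predict(Xtr, ytr, X[i, , drop = FALSE], tuned_cfg,
                        classifier),
        error = function(e) stop("jackknife fold ", i, ": ",
                                 conditionMessage(e), call. = FALSE))
    }
  }
  meta$model_seed <- model_cfg$seed
  evaluation_report(y, pred, levels(y), protocol = meta)
}

# grid-search (cost, gamma) once on the supplied data and return a 1x1-grid
# config that reuses the winner in every fold
tune_once <- function(X, y, model_cfg, classifier) {
  if (classifier != "svm") return(model_cfg)
  if (length(model_cfg$c_grid) == 1L && length(model_cfg$gamma_grid) == 1L)
    return(model_cfg)
  full <- hsp_train(X, y, model_cfg)
  model_config(c_grid = full$cost, gamma_grid = full$gamma,
               scaling = model_cfg$scaling,
               inner_cv_folds = model_cfg$inner_cv_folds,
               seed = model_cfg$seed)
}

#' k-fold cross-validation of the HSP pipeline
#'
#' A cheaper alternative to [jackknife()] with the same protocols and
#' metric suite, using stratified folds.
#'
#' @inheritParams jackknife
#' @param folds Number of stratified folds.
#' @param seed Seed for the fold assignment.
#' @return An `"evaluation_report"`.
#' @export
cross_validate <- function(X, y, model_cfg = model_config(),
                           smote_cfg = NULL, folds = 5L,
                           protocol = c("as-paper", "leakage-safe"),
                           classifier = c("svm", "majority"), seed = 1L) {
  protocol <- match.arg(protocol)
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  y <- factor(y)
  y <- factor(y, levels = sort(levels(y)))
  meta <- list(protocol = paste0(folds, "-fold CV"),
               smote_placement = protocol, smote = !is.null(smote_cfg),
               classifier = classifier, seed = seed)
  if (protocol == "as-paper" && !is.null(smote_cfg)) {
    bal <- balance_to_majority(X, y, smote_cfg)
    X <- bal$X
    y <- bal$y
  }
  fold_id <- stratified_folds(y, folds, seed)
  tuned_cfg <- tune_once(X, y, model_cfg, classifier)
  pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
  for (f in seq_len(folds)) {
    te <- fold_id == f
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y[!te]
    if (protocol == "leakage-safe" && !is.null(smote_cfg)) {
      bal <- balance_to_majority(Xtr, ytr, smote_cfg)
      Xtr <- bal$X
      ytr <- bal$y
    }
    pred[te] <- fit_and_predict(Xtr, ytr, X[te, , drop = FALSE],
                                tuned_cfg, classifier)
  }
  evaluation_report(y, pred, levels(y), protocol = meta)
}

#' Evaluate a trained model on an independent test set
#'
#' @param model An [hsp_train()] model.
#' @param X Test feature matrix.
#' @param y True test labels (values within the model's `label_set`).
#' @param train_ids Optional ids of the training samples; overlap with
#'   `rownames(X)` triggers a warning (an independent test set must be
#'   disjoint from training).
#' @return An `"evaluation_report"`.
#' @export
evaluate_independent <- function(model, X, y, train_ids = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty test set", call. = FALSE)
  if (!is.null(train_ids) && !is.null(rownames(X))) {
    overlap <- intersect(train_ids, rownames(X))
    if (length(overlap) > 0L)
      warning("test ids overlap training ids: ",
              paste(utils::head(overlap, 5L), collapse = ", "),
              if (length(overlap) > 5L) ", ..." else "", call. = FALSE)
  }
  pred <- predict(model, X)
  evaluation_report(factor(as.character(y), levels = model$label_set),
                    pred, model$label_set,
                    protocol = list(protocol = "independent"))
}
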