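test_that("per-class metrics evaluate the defining formulas", {
  perfect <- class_metrics(10, 90, 0, 0)
  expect_equal(unlist(perfect[c("Sn", "Sp", "MCC", "Acc")]),
               c(Sn = 1, Sp = 1, MCC = 1, Acc = 1))
  m <- class_metrics(8, 85, 5, 2)
  o <- oracle_metrics(8, 85, 5, 2)
  expect_equal(m$Sn, 0.8)
  expect_equal(m$Sp, o$Sp)
  expect_equal(m$MCC, o$MCC)
  expect_equal(m$Acc, 0.93)
  # anti-classifier: everything systematically wrong
  anti <- class_metrics(0, 0, 90, 10)
  expect_equal(anti$Sn, 0)
  expect_equal(anti$Sp, 0)
  expect_lte(anti$MCC, 0)
  expect_error(class_metrics(0, 0, 0, 0), "zero")
})

test_that("a zero MCC denominator is defined as 0 and flagged", {
  m <- class_metrics(0, 10, 0, 0)  # no positives anywhere
  expect_equal(m$MCC, 0)
  expect_true(m$mcc_zero_denominator)
  expect_false(class_metrics(5, 5, 1, 1)$mcc_zero_denominator)
})

test_that("metrics match an independent re-implementation on random counts", {
  set.seed(17)
  for (i in 1:200) {
    cnt <- stats::rpois(4, lambda = sample(c(2, 20, 200), 1))
    if (sum(cnt) == 0) cnt[1] <- 1
    m <- class_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    o <- oracle_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    for (k in c("Sn", "Sp", "MCC", "Acc"))
      if (!is.na(o[[k]])) expect_equal(m[[k]], o[[k]], tolerance = 1e-12)
  }
})

test_that("confusion matrices reduce to one-vs-rest counts correctly", {
  yt <- c("a", "a", "a", "b", "b", "b", "b", "b")
  yp <- c("a", "a", "b", "b", "b", "b", "b", "a")
  cf <- confusion_from_predictions(yt, yp, c("a", "b"))
  expect_equal(as.vector(cf$confusion), c(2L, 1L, 1L, 4L))
  a <- cf$counts[cf$counts$class == "a", ]
  expect_equal(c(a$TP, a$TN, a$FP, a$FN), c(2L, 4L, 1L, 1L))
  # perfect predictions give a diagonal matrix; TP sum equals the trace
  cf2 <- confusion_from_predictions(yt, yt, c("a", "b"))
  expect_equal(sum(cf2$confusion) - sum(diag(cf2$confusion)), 0)
  expect_equal(sum(cf2$counts$TP), sum(diag(cf2$confusion)))
  expect_error(confusion_from_predictions(yt, yp[-1], c("a", "b")),
               "lengths differ")
  expect_error(confusion_from_predictions(yt, c(yp[-1], "z"), c("a", "b")),
               "label_set")
})

test_that("report OA equals the TP-sum identity and the label proportions", {
  set.seed(23)
  labs <- c("x", "y", "z")
  yt <- sample(labs, 60, replace = TRUE)
  yp <- ifelse(stats::runif(60) < 0.7, yt, sample(labs, 60, replace = TRUE))
  rep <- hspfam:::evaluation_report(yt, yp, labs)
  expect_equal(rep$OA, sum(rep$per_class$TP) / rep$N)
  expect_equal(rep$OA, mean(yt == yp))
  expect_true(all(rep$per_class$Sn >= 0 & rep$per_class$Sn <= 1))
  expect_true(all(rep$per_class$MCC >= -1 & rep$per_class$MCC <= 1))
})

test_that("jackknife with a majority-vote dummy reproduces the analytic baseline", {
  g <- gauss_classes(c(12, 5, 3), d = 3, sep = 1, seed = 2)
  rep <- jackknife(g$X, g$y, classifier = "majority")
  expect_equal(rep$OA, 12 / 20)
  expect_equal(rep$N, 20)
})

test_that("as-paper jackknife evaluates every sample of the balanced set", {
  g <- gauss_classes(c(10, 6), d = 3, sep = 6, seed = 5)
  rep <- jackknife(g$X, g$y, model_config(c_grid = 2, gamma_grid = 0.25),
                   smote_cfg = smote_config(seed = 1))
  expect_equal(rep$N, 20)  # balanced to 2 x 10
  expect_identical(rep$protocol$smote_placement, "as-paper")
  expect_true(rep$protocol$smote)
})

test_that("jackknife recovers perfectly separable classes", {
  g <- gauss_classes(c(9, 8, 7), d = 4, sep = 8, seed = 7)
  rep <- jackknife(g$X, g$y, fast_model_cfg(seed = 7))
  expect_equal(rep$OA, 1)
  expect_equal(unname(rep$per_class$Sn), rep(1, 3))
})

test_that("jackknife is deterministic given seeds", {
  g <- gauss_classes(c(8, 6, 5), d = 3, sep = 3, seed = 9)
  r1 <- jackknife(g$X, g$y, fast_model_cfg(seed = 2),
                  smote_cfg = smote_config(seed = 2))
  r2 <- jackknife(g$X, g$y, fast_model_cfg(seed = 2),
                  smote_cfg = smote_config(seed = 2))
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(r1$OA, r2$OA)
})

test_that("k-fold cross-validation mirrors the jackknife contracts", {
  g <- gauss_classes(c(10, 8, 8), d = 4, sep = 8, seed = 3)
  rep <- cross_validate(g$X, g$y, fast_model_cfg(seed = 3), folds = 4,
                        seed = 3)
  expect_equal(rep$OA, 1)
  expect_equal(rep$N, 26)
  repm <- cross_validate(g$X, g$y, folds = 4, classifier = "majority",
                         seed = 3)
  expect_true(repm$OA <= 10 / 26 + 1e-9)
})

test_that("independent evaluation is consistent with its confusion matrix", {
  g <- gauss_classes(c(10, 9), d = 3, sep = 7, seed = 8)
  rownames(g$X) <- paste0("tr", seq_len(nrow(g$X)))
  m <- hsp_train(g$X, g$y, model_config(c_grid = 2, gamma_grid = 0.1))
  rep <- evaluate_independent(m, g$X, g$y)
  expect_equal(rep$OA, 1)  # training set of a separable model
  one <- evaluate_independent(m, g$X[1, , drop = FALSE], g$y[1])
  expect_true(one$OA %in% c(0, 1))
  pred <- predict(m, g$X)
  cf <- confusion_from_predictions(g$y, pred, m$label_set)
  expect_identical(unclass(rep$confusion), unclass(cf$confusion))
  expect_error(evaluate_independent(m, g$X[0, , drop = FALSE], g$y[0]),
               "empty")
  expect_warning(evaluate_independent(m, g$X, g$y,
                                      train_ids = rownames(g$X)),
                 "overlap")
})

test_that("reports serialise to JSON with protocol metadata", {
  g <- gauss_classes(c(6, 6), d = 3, sep = 6, seed = 4)
  rep <- jackknife(g$X, g$y, model_config(c_grid = 2, gamma_grid = 0.1))
  f <- tempfile(fileext = ".json")
  report_to_json(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$OA, rep$OA)
  expect_equal(back$N, 12)
  expect_identical(back$protocol$protocol, "jackknife")
})
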