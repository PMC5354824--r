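test_that("metric set reproduces the printed special cases", {
  perfect <- compute_metrics(confusion_counts(100, 100, fn = 0, fp = 0))
  expect_equal(perfect$sn, 1)
  expect_equal(perfect$sp, 1)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$mcc, 1)

  half <- compute_metrics(confusion_counts(100, 100, fn = 50, fp = 50))
  expect_equal(half$acc, 0.5)
  expect_equal(half$mcc, 0)

  total <- compute_metrics(confusion_counts(100, 100, fn = 100, fp = 100))
  expect_equal(total$acc, 0)
  expect_equal(total$mcc, -1)

  # asymmetric edge: no missed positives, all negatives wrong; every sample
  # is predicted positive, so the MCC denominator degenerates
  expect_warning(
    asym <- compute_metrics(confusion_counts(50, 80, fn = 0, fp = 80)),
    "MCC")
  expect_equal(asym$mcc, 0)
  expect_equal(asym$sn, 1)
  expect_equal(asym$sp, 0)
  expect_true(equivalence_check(confusion_counts(50, 80, fn = 0, fp = 80)))
})

test_that("intuitive and conventional formulations agree across the count lattice", {
  for (fn in 0:20) {
    for (fp in 0:20) {
      counts <- confusion_counts(20, 20, fn = fn, fp = fp)
      expect_true(equivalence_check(counts))
      m <- suppressWarnings(compute_metrics(counts))
      o <- oracle_metrics(20, 20, fn, fp)
      expect_equal(m$sn, o$sn, tolerance = 1e-12)
      expect_equal(m$sp, o$sp, tolerance = 1e-12)
      expect_equal(m$acc, o$acc, tolerance = 1e-12)
      expect_equal(m$mcc, o$mcc, tolerance = 1e-12)
    }
  }
  # unequal class sizes too
  set.seed(17)
  for (rep in 1:30) {
    n_pos <- sample(5:40, 1); n_neg <- sample(5:40, 1)
    expect_true(equivalence_check(
      confusion_counts(n_pos, n_neg, sample(0:n_pos, 1), sample(0:n_neg, 1))))
  }
})

test_that("degenerate all-one-class predictions give MCC 0 with a warning", {
  counts <- confusion_counts(30, 10, fn = 30, fp = 0)
  expect_warning(m <- compute_metrics(counts), "MCC")
  expect_equal(m$mcc, 0)
})

test_that("label swap exchanges Sn and Sp and preserves Acc and |MCC| for balanced classes", {
  set.seed(18)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    fn <- sample(0:n, 1); fp <- sample(0:n, 1)
    a <- suppressWarnings(compute_metrics(confusion_counts(n, n, fn, fp)))
    b <- suppressWarnings(compute_metrics(confusion_counts(n, n, fp, fn)))
    expect_equal(a$sn, b$sp)
    expect_equal(a$sp, b$sn)
    expect_equal(a$acc, b$acc)
    expect_equal(abs(a$mcc), abs(b$mcc))
  }
})

test_that("validation of confusion counts rejects impossible values", {
  expect_error(confusion_counts(0, 10, 0, 0), "non-empty")
  expect_error(confusion_counts(10, 10, 11, 0), "exceed")
  expect_error(confusion_counts(10, 10, -1, 0), "non-negative")
})

test_that("jackknife is exact on separable data and invariant to row order", {
  set.seed(19)
  toy <- toy_separable_windows(n_per_class = 2, xi = 3)
  res <- jackknife(toy, C = 4, gamma = 0.1)
  expect_equal(res$metrics$acc, 1)

  ds <- simulate_editing_windows(n_pos = 12, n_neg = 12, xi = 6,
                                 signal_strength = 0.6, seed = 23)
  a <- jackknife(ds, C = 2, gamma = 0.05)
  b <- jackknife(ds[sample(nrow(ds)), ], C = 2, gamma = 0.05)
  expect_identical(glance(a), glance(b))
  expect_identical(a$predictions, b$predictions)
})

test_that("jackknife matches an independently written leave-one-out loop", {
  ds <- simulate_editing_windows(n_pos = 10, n_neg = 10, xi = 5,
                                 signal_strength = 1, seed = 29)
  C <- 2; gamma <- 0.02
  res <- jackknife(ds, C = C, gamma = gamma)

  # naive oracle: explicit loop over held-out indices on the same canonical
  # ordering, calling the SVM backend directly
  ord <- order(ds$residues, ds$label, ds$source_id, ds$center_pos)
  ds_o <- ds[ord, ]
  feat <- t(sapply(ds_o$residues, function(r) vectorize(r)))
  lab <- factor(ds_o$label, levels = c("pos", "neg"))
  oracle_pred <- character(nrow(ds_o))
  for (i in seq_len(nrow(ds_o))) {
    fit <- e1071::svm(feat[-i, ], lab[-i], type = "C-classification",
                      kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE)
    oracle_pred[i] <- as.character(predict(fit, feat[i, , drop = FALSE]))
  }
  expect_equal(res$predictions$prediction, oracle_pred)
  o_counts <- confusion_counts(
    n_pos = sum(lab == "pos"), n_neg = sum(lab == "neg"),
    fn = sum(lab == "pos" & oracle_pred == "neg"),
    fp = sum(lab == "neg" & oracle_pred == "pos"))
  o_m <- suppressWarnings(compute_metrics(o_counts))
  expect_equal(res$metrics$acc, o_m$acc)
  expect_equal(res$metrics$mcc, o_m$mcc)
})

test_that("k-fold is seed-stable, stratified, and reduces to jackknife at k = n", {
  ds <- simulate_editing_windows(n_pos = 8, n_neg = 8, xi = 4,
                                 signal_strength = 1, seed = 31)
  a <- kfold(ds, k = 4, C = 2, gamma = 0.05, seed = 7)
  b <- kfold(ds, k = 4, C = 2, gamma = 0.05, seed = 7)
  expect_identical(glance(a)[, -1], glance(b)[, -1])

  loo <- kfold(ds, k = nrow(ds), C = 2, gamma = 0.05, seed = 1)
  jk <- jackknife(ds, C = 2, gamma = 0.05)
  expect_equal(loo$metrics$acc, jk$metrics$acc)
  expect_equal(loo$predictions$prediction, jk$predictions$prediction)

  expect_error(kfold(ds, k = 12, C = 1, gamma = 0.05, seed = 1),
               "fewer folds")
  expect_error(kfold(ds, k = 1, C = 1, gamma = 0.05, seed = 1), "at least 2")
})

test_that("independent evaluation enforces disjointness, xi, and non-emptiness", {
  set.seed(33)
  train <- toy_separable_windows(n_per_class = 6, xi = 3)
  m <- svm_train(train, C = 4, gamma = 0.1)

  expect_error(independent_test(m, train, training_windows = train),
               "overlap")
  # scoring the training set itself is possible with the override and is at
  # least as good as jackknife on separable toys
  self <- independent_test(m, train, training_windows = train,
                           allow_overlap = TRUE)
  jk <- jackknife(train, C = 4, gamma = 0.1)
  expect_gte(self$metrics$acc, jk$metrics$acc)

  expect_error(independent_test(m, train[0, ]), "empty")
})

test_that("evaluation reports are written with metrics and per-sample predictions", {
  toy <- toy_separable_windows(n_per_class = 3, xi = 2)
  res <- jackknife(toy, C = 2, gamma = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eval_report(res, path)
  rep_df <- utils::read.csv(path)
  expect_equal(rep_df$protocol, "jackknife")
  expect_equal(rep_df$acc, res$metrics$acc)
  preds <- utils::read.csv(sub("\\.csv$", "_predictions.csv", path))
  expect_equal(nrow(preds), 6)
  expect_true(all(c("source_id", "center_pos", "label", "prediction",
                    "score") %in% names(preds)))
})

test_that("tidy and glance return broom-shaped tibbles", {
  toy <- toy_separable_windows(n_per_class = 3, xi = 2)
  res <- jackknife(toy, C = 2, gamma = 0.2)
  td <- tidy(res)
  expect_equal(td$metric, c("sn", "sp", "acc", "mcc"))
  expect_true(all(td$value >= -1 & td$value <= 1))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_pos, 3)

  m <- svm_train(toy, C = 2, gamma = 0.2)
  expect_equal(glance(m)$n_features, 4 * 5)
})
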