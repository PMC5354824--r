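#' Confusion counts for a binary editing-site predictor
#'
#' Bundles the four counts of the intuitive metric formulation: the class
#' totals and the two kinds of misclassification. `fn` is the number of true
#' editing samples predicted as non-sites; `fp` the number of non-sites
#' predicted as editing sites.
#'
#' @param n_pos,n_neg Total positive / negative samples (both > 0).
#' @param fn,fp Misclassified positives / negatives.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(n_pos, n_neg, fn, fp) {
  vals <- c(n_pos = n_pos, n_neg = n_neg, fn = fn, fp = fp)
  if (any(vals != round(vals)) || any(vals < 0)) {
    abort("Counts must be non-negative integers",
          class = "inosine_invalid_input")
  }
  if (n_pos <= 0 || n_neg <= 0) {
    abort("Both classes must be non-empty", class = "inosine_invalid_input")
  }
  if (fn > n_pos || fp > n_neg) {
    abort("Misclassification counts cannot exceed class totals",
          class = "inosine_invalid_input")
  }
  structure(as.list(vals), class = "confusion_counts")
}

# Tally confusion counts from truth/prediction label vectors.
tally_counts <- function(truth, predicted) {
  confusion_counts(
    n_pos = sum(truth == "pos"), n_neg = sum(truth == "neg"),
    fn = sum(truth == "pos" & predicted == "neg"),
    fp = sum(truth == "neg" & predicted == "pos")
  )
}

#' Sensitivity, specificity, accuracy, and MCC from confusion counts
#'
#' Uses the intuitive formulation: with class totals `N+`, `N-` and
#' misclassification counts `fn` (positives called negative) and `fp`
#' (negatives called positive),
#' \deqn{Sn = 1 - fn/N^+, \quad Sp = 1 - fp/N^-,}
#' \deqn{Acc = 1 - (fn + fp)/(N^+ + N^-),}
#' \deqn{MCC = \frac{1 - (fn/N^+ + fp/N^-)}
#'   {\sqrt{(1 + (fp - fn)/N^+)(1 + (fn - fp)/N^-)}}.}
#' These are algebraically identical to the conventional TP/TN/FP/FN
#' formulas (see [equivalence_check()]). Zero misclassification gives
#' Acc = 1 and MCC = 1; misclassifying half of each class gives Acc = 0.5 and
#' MCC = 0 (no better than random guessing); total misclassification gives
#' Acc = 0 and MCC = -1. When the MCC denominator vanishes (every sample
#' assigned to one class with unequal class sizes) the MCC is reported as 0
#' with a warning, the usual convention for the degenerate case.
#'
#' @param counts A [confusion_counts()] object.
#' @return An object of class `metric_set`: a list with `sn`, `sp`, `acc`,
#'   `mcc` and the counts.
#' @export
#' @examples
#' compute_metrics(confusion_counts(100, 100, fn = 0, fp = 0))
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n_pos <- counts$n_pos; n_neg <- counts$n_neg
  fn <- counts$fn; fp <- counts$fp
  sn <- 1 - fn / n_pos
  sp <- 1 - fp / n_neg
  acc <- 1 - (fn + fp) / (n_pos + n_neg)
  denom_sq <- (1 + (fp - fn) / n_pos) * (1 + (fn - fp) / n_neg)
  num <- 1 - (fn / n_pos + fp / n_neg)
  if (denom_sq <= 0 || sqrt(denom_sq) == 0) {
    warn("MCC denominator is zero (all samples predicted as one class); reporting MCC = 0")
    mcc <- 0
  } else {
    mcc <- num / sqrt(denom_sq)
  }
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc, counts = counts),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Sn = %.2f%%  Sp = %.2f%%  Acc = %.2f%%  MCC = %.2f\n",
              100 * x$sn, 100 * x$sp, 100 * x$acc, x$mcc))
  invisible(x)
}

#' Check the intuitive metrics against the conventional formulation
#'
#' Recomputes Sn, Sp, Acc, and MCC from TP = `n_pos - fn`, TN = `n_neg - fp`,
#' FP = `fp`, FN = `fn` using the textbook formulas and compares with the
#' intuitive formulation.
#'
#' @param counts A [confusion_counts()] object.
#' @param tol Agreement tolerance (default 1e-12).
#' @return `TRUE` when every metric agrees within `tol`.
#' @export
equivalence_check <- function(counts, tol = 1e-12) {
  stopifnot(inherits(counts, "confusion_counts"))
  m <- suppressWarnings(compute_metrics(counts))
  tp <- counts$n_pos - counts$fn; fn <- counts$fn
  tn <- counts$n_neg - counts$fp; fp <- counts$fp
  sn_c <- tp / (tp + fn)
  sp_c <- tn / (tn + fp)
  acc_c <- (tp + tn) / (tp + tn + fp + fn)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc_c <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  all(abs(c(m$sn - sn_c, m$sp - sp_c, m$acc - acc_c, m$mcc - mcc_c)) <= tol)
}

# Canonical ordering making resampling protocols independent of input order.
canonical_order <- function(windows) {
  windows[order(windows$residues, windows$label, windows$source_id,
                windows$center_pos), , drop = FALSE]
}

#' Jackknife (leave-one-out) evaluation
#'
#' For each sample in turn, trains on all remaining samples at the fixed
#' (C, gamma) and predicts the held-out sample; confusion counts are pooled
#' over all rounds. The dataset is put into a canonical order first, so the
#' outcome is unique for a given dataset and parameters regardless of row
#' order.
#'
#' @param windows A labeled window tibble with at least two samples per class.
#' @param C,gamma SVM hyperparameters.
#' @return An object of class `ai_eval`: the `metric_set` plus a per-sample
#'   prediction tibble (`source_id`, `center_pos`, `label`, `prediction`,
#'   `score`) and protocol metadata.
#' @export
jackknife <- function(windows, C, gamma) {
  check_window_tibble(windows, need_label = TRUE)
  if (min(table(windows$label)) < 2 || length(unique(windows$label)) < 2) {
    abort("Jackknife needs at least two samples of each class",
          class = "inosine_invalid_input")
  }
  ds <- canonical_order(windows)
  features <- encode_windows(ds)
  labels <- factor(ds$label, levels = c("pos", "neg"))
  n <- nrow(ds)
  pred <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    fit <- e1071::svm(features[-i, , drop = FALSE], labels[-i],
                      type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    p <- stats::predict(fit, features[i, , drop = FALSE],
                        decision.values = TRUE)
    dv <- attr(p, "decision.values")
    s <- as.numeric(dv[, 1])
    if (colnames(dv)[[1]] == "neg/pos") s <- -s
    score[[i]] <- s
    pred[[i]] <- ifelse(s > 0, "pos", "neg")
  }
  build_eval(ds, pred, score, protocol = "jackknife", C = C, gamma = gamma)
}

#' Stratified k-fold cross-validation
#'
#' Splits each class into k folds drawn from the seed (fold sizes within a
#' class differ by at most one), trains on k-1 folds and predicts the held
#' out fold, pooling confusion counts over folds. `k` equal to the dataset
#' size is the leave-one-out limit and is dispatched to [jackknife()];
#' any other `k` exceeding the smaller class count is an error.
#'
#' @inheritParams jackknife
#' @param k Number of folds (at least 2).
#' @param seed Integer seed for the fold draw.
#' @return An `ai_eval` object.
#' @export
kfold <- function(windows, k, C, gamma, seed = 1) {
  check_window_tibble(windows, need_label = TRUE)
  if (k < 2) abort("`k` must be at least 2", class = "inosine_invalid_input")
  n <- nrow(windows)
  if (k == n) {
    out <- jackknife(windows, C, gamma)
    out$protocol <- "kfold"
    out$k <- k
    return(out)
  }
  ds <- canonical_order(windows)
  folds <- make_stratified_folds(ds$label, k, seed)
  features <- encode_windows(ds)
  labels <- factor(ds$label, levels = c("pos", "neg"))
  pred <- character(n)
  score <- numeric(n)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    fit <- e1071::svm(features[-test, , drop = FALSE], labels[-test],
                      type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    p <- stats::predict(fit, features[test, , drop = FALSE],
                        decision.values = TRUE)
    dv <- attr(p, "decision.values")
    s <- as.numeric(dv[, 1])
    if (colnames(dv)[[1]] == "neg/pos") s <- -s
    score[test] <- s
    pred[test] <- ifelse(s > 0, "pos", "neg")
  }
  out <- build_eval(ds, pred, score, protocol = "kfold", C = C, gamma = gamma)
  out$k <- k
  out$seed <- seed
  out
}

#' Independent-dataset evaluation
#'
#' Applies a trained model to a dataset that must be disjoint from its
#' training data and reports the metric set. Disjointness is checked with
#' [assert_disjoint()] when the model's training windows are supplied;
#' set `allow_overlap = TRUE` to deliberately score a model on overlapping
#' (e.g. its own training) data.
#'
#' @param model An `ai_svm` model.
#' @param windows A labeled window tibble with the model's xi.
#' @param training_windows Optional window tibble the model was trained on,
#'   used for the disjointness check.
#' @param allow_overlap Skip the disjointness check (default `FALSE`).
#' @return An `ai_eval` object.
#' @export
independent_test <- function(model, windows, training_windows = NULL,
                             allow_overlap = FALSE) {
  stopifnot(inherits(model, "ai_svm"))
  check_window_tibble(windows, need_label = TRUE)
  if (nrow(windows) == 0) {
    abort("Independent dataset is empty", class = "inosine_invalid_input")
  }
  if (!is.na(model$xi) && windows$xi[[1]] != model$xi) {
    abort(paste0("Model xi = ", model$xi, " does not match dataset xi = ",
                 windows$xi[[1]]), class = "inosine_invalid_input")
  }
  if (!allow_overlap && !is.null(training_windows) &&
      !assert_disjoint(windows, training_windows)) {
    abort("Dataset overlaps the model's training set; use allow_overlap = TRUE to score anyway",
          class = "inosine_invalid_input")
  }
  p <- stats::predict(model, windows)
  build_eval(windows, p$label, p$score, protocol = "independent",
             C = model$C, gamma = model$gamma)
}

build_eval <- function(ds, pred, score, protocol, C, gamma) {
  counts <- tally_counts(ds$label, pred)
  metrics <- compute_metrics(counts)
  structure(
    list(metrics = metrics,
         predictions = tibble(source_id = ds$source_id,
                              center_pos = ds$center_pos,
                              label = ds$label, prediction = pred,
                              score = score),
         protocol = protocol, C = C, gamma = gamma),
    class = "ai_eval"
  )
}

#' @export
print.ai_eval <- function(x, ...) {
  cat(sprintf("%s evaluation (C = %g, gamma = %g, n = %d)\n",
              x$protocol, x$C, x$gamma, nrow(x$predictions)))
  print(x$metrics)
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes a headered CSV of the metric set (with counts, protocol, and
#' hyperparameters) and, alongside it, a per-sample prediction table
#' `<path stem>_predictions.csv`.
#'
#' @param eval_result An `ai_eval` object.
#' @param path Output CSV path for the metrics.
#' @return The metrics path, invisibly.
#' @export
write_eval_report <- function(eval_result, path) {
  stopifnot(inherits(eval_result, "ai_eval"))
  g <- glance(eval_result)
  utils::write.csv(g, path, row.names = FALSE)
  pred_path <- sub("(\\.[^.]*)?$", "_predictions.csv", path)
  utils::write.csv(eval_result$predictions, pred_path, row.names = FALSE)
  invisible(path)
}
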