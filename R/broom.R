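#' Tidy an evaluation result
#'
#' One row per metric (`sn`, `sp`, `acc`, `mcc`) with its value; `sn`, `sp`,
#' and `acc` also carry the percent display value used in reports.
#'
#' @param x An `ai_eval` or `metric_set` object.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `value`, `percent`.
#' @export
tidy.ai_eval <- function(x, ...) tidy(x$metrics, ...)

#' @rdname tidy.ai_eval
#' @export
tidy.metric_set <- function(x, ...) {
  tibble(
    metric = c("sn", "sp", "acc", "mcc"),
    value = c(x$sn, x$sp, x$acc, x$mcc),
    percent = c(100 * x$sn, 100 * x$sp, 100 * x$acc, NA_real_)
  )
}

#' Glance at an evaluation result
#'
#' @param x An `ai_eval` object.
#' @param ... Unused.
#' @return A one-row tibble with the protocol, hyperparameters, confusion
#'   counts, and the four metrics.
#' @export
glance.ai_eval <- function(x, ...) {
  counts <- x$metrics$counts
  tibble(
    protocol = x$protocol, C = x$C, gamma = x$gamma,
    n_pos = counts$n_pos, n_neg = counts$n_neg,
    fn = counts$fn, fp = counts$fp,
    sn = x$metrics$sn, sp = x$metrics$sp,
    acc = x$metrics$acc, mcc = x$metrics$mcc
  )
}

#' Tidy a grid-search result
#'
#' @param x An `ai_grid` object.
#' @param ... Unused.
#' @return The full cross-validation table: one row per (C, gamma) pair with
#'   its inner-CV accuracy.
#' @export
tidy.ai_grid <- function(x, ...) as_tibble(x$cv_table)

#' Glance at a grid-search result
#'
#' @param x An `ai_grid` object.
#' @param ... Unused.
#' @return A one-row tibble with the selected pair and its accuracy.
#' @export
glance.ai_grid <- function(x, ...) {
  tibble(C = x$C, gamma = x$gamma, accuracy = x$best_accuracy,
         n_pairs = nrow(x$cv_table), inner_folds = x$inner_folds)
}

#' Glance at a trained model
#'
#' @param x An `ai_svm` object.
#' @param ... Unused.
#' @return A one-row tibble with hyperparameters, dimensions, and support
#'   vector count.
#' @export
glance.ai_svm <- function(x, ...) {
  tibble(C = x$C, gamma = x$gamma, xi = x$xi, n_features = x$n_features,
         n_train = x$n_train, n_support = x$fit$tot.nSV)
}
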