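MODEL_FORMAT_VERSION <- "inosine-model-1"

#' Hyperparameter grid for the RBF support-vector classifier
#'
#' Candidate values are powers of `base` over integer exponent lattices:
#' cost C over `base^c_exponents` and kernel width gamma over
#' `base^gamma_exponents`. The defaults give the classical 21 x 11 = 231-pair
#' search: C from 2^-5 to 2^15 and gamma from 2^-15 to 2^-5, stepping the
#' exponent by 1.
#'
#' @param c_exponents Integer exponents for C (default `-5:15`).
#' @param gamma_exponents Integer exponents for gamma (default `-15:-5`).
#' @param base Base of the lattice (default 2).
#' @return An object of class `grid_spec` with the candidate values.
#' @export
#' @examples
#' g <- grid_spec()
#' length(g$C) * length(g$gamma) # 231
grid_spec <- function(c_exponents = -5:15, gamma_exponents = -15:-5,
                      base = 2) {
  stopifnot(is.numeric(c_exponents), is.numeric(gamma_exponents),
            length(c_exponents) > 0, length(gamma_exponents) > 0)
  structure(
    list(c_exponents = as.integer(c_exponents),
         gamma_exponents = as.integer(gamma_exponents),
         base = base,
         C = base^as.integer(c_exponents),
         gamma = base^as.integer(gamma_exponents)),
    class = "grid_spec"
  )
}

# Resolve window tibble vs plain matrix input into (features, labels, xi).
resolve_training_input <- function(x, labels = NULL) {
  if (is.data.frame(x)) {
    check_window_tibble(x, need_label = TRUE)
    features <- encode_windows(x)
    labels <- x$label
    xi <- if (nrow(x) > 0) x$xi[[1]] else NA_integer_
  } else {
    features <- as.matrix(x)
    if (is.null(labels)) {
      abort("`labels` must be supplied with a feature matrix",
            class = "inosine_invalid_input")
    }
    xi <- NA_integer_
  }
  if (!all(is.finite(features))) {
    abort("Features must be finite", class = "inosine_invalid_input")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("pos", "neg"))) {
    abort("Labels must be \"pos\" or \"neg\"", class = "inosine_invalid_input")
  }
  if (length(unique(labels)) < 2) {
    abort("Training data must contain both classes",
          class = "inosine_invalid_input")
  }
  list(features = features, labels = factor(labels, levels = c("pos", "neg")),
       xi = xi)
}

#' Train an RBF-kernel support-vector classifier
#'
#' Fits a C-SVM with radial basis kernel at fixed cost and kernel width.
#' Features are used as-is (every channel of the encoding already lies in
#' `[0, 1]`, so no scaling is applied). Training is deterministic for a fixed
#' input.
#'
#' @param x A labeled window tibble (features are computed with
#'   [encode_windows()]), or a numeric feature matrix.
#' @param labels Character/factor labels (`"pos"`/`"neg"`), required when `x`
#'   is a matrix; ignored for window tibbles.
#' @param C Cost parameter (positive).
#' @param gamma RBF kernel width parameter (positive).
#' @param meta Optional named list stored with the model (e.g. dataset tag,
#'   seed).
#' @return An object of class `ai_svm`.
#' @export
svm_train <- function(x, labels = NULL, C = 1, gamma = NULL, meta = list()) {
  inp <- resolve_training_input(x, labels)
  if (!is.numeric(C) || C <= 0 || !is.finite(C)) {
    abort("`C` must be a positive finite number",
          class = "inosine_invalid_input")
  }
  if (is.null(gamma)) gamma <- 1 / ncol(inp$features)
  if (!is.numeric(gamma) || gamma <= 0 || !is.finite(gamma)) {
    abort("`gamma` must be a positive finite number",
          class = "inosine_invalid_input")
  }
  fit <- e1071::svm(inp$features, inp$labels, type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  structure(
    list(fit = fit, C = C, gamma = gamma, xi = inp$xi,
         n_features = ncol(inp$features), n_train = nrow(inp$features),
         meta = meta, timestamp = format(Sys.time(), tz = "UTC"),
         version = MODEL_FORMAT_VERSION),
    class = "ai_svm"
  )
}

#' @export
print.ai_svm <- function(x, ...) {
  cat("RBF-SVM A-to-I editing-site model\n")
  cat(sprintf("  C = %g, gamma = %g\n", x$C, x$gamma))
  cat(sprintf("  %d features (xi = %s), %d training samples, %d SVs\n",
              x$n_features, ifelse(is.na(x$xi), "?", x$xi), x$n_train,
              x$fit$tot.nSV))
  invisible(x)
}

#' Predict editing labels for new windows
#'
#' Returns the predicted class and the signed decision value for each sample;
#' a sample is called positive exactly when its decision score is greater
#' than zero. Predictions are row-order equivariant.
#'
#' @param object An `ai_svm` model.
#' @param newdata A window tibble or a feature matrix with the model's
#'   feature dimension.
#' @param ... Unused.
#' @return A tibble with columns `label` (`"pos"`/`"neg"`) and `score`;
#'   window-tibble input also carries `source_id` and `center_pos`.
#' @export
predict.ai_svm <- function(object, newdata, ...) {
  provenance <- NULL
  if (is.data.frame(newdata)) {
    check_window_tibble(newdata)
    if (nrow(newdata) > 0 && !is.na(object$xi) &&
        newdata$xi[[1]] != object$xi) {
      abort(paste0("Model was trained with xi = ", object$xi,
                   " but windows have xi = ", newdata$xi[[1]]),
            class = "inosine_invalid_input")
    }
    provenance <- newdata[, c("source_id", "center_pos")]
    features <- encode_windows(newdata)
  } else {
    features <- as.matrix(newdata)
  }
  if (nrow(features) == 0) {
    out <- tibble(label = character(), score = numeric())
    if (!is.null(provenance)) out <- dplyr::bind_cols(provenance, out)
    return(out)
  }
  if (ncol(features) != object$n_features) {
    abort(paste0("Feature dimension mismatch: model expects ",
                 object$n_features, ", got ", ncol(features)),
          class = "inosine_invalid_input")
  }
  pred <- stats::predict(object$fit, features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- as.numeric(dv[, 1])
  # libsvm reports the decision value for the class pair named in the column;
  # flip so that positive score always means the "pos" class
  if (colnames(dv)[[1]] == "neg/pos") score <- -score
  out <- tibble(label = ifelse(score > 0, "pos", "neg"), score = score)
  if (!is.null(provenance)) out <- dplyr::bind_cols(provenance, out)
  out
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin, so fold sizes differ by at most one per class.
make_stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (k > min(counts)) {
    abort(paste0("Cannot build ", k, " stratified folds with class counts ",
                 paste(counts, collapse = "/"),
                 "; use fewer folds"),
          class = "inosine_invalid_input")
  }
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Tune C and gamma by grid search
#'
#' Evaluates every (C, gamma) pair of the grid by stratified inner k-fold
#' cross-validated accuracy on the supplied data and returns the maximizing
#' pair together with the full score table. Ties are broken toward the
#' smallest C, then the smallest gamma. The folds are drawn once from the
#' seed and reused for every pair, so the search is deterministic.
#'
#' @inheritParams svm_train
#' @param grid A [grid_spec()] (default: the full 231-pair lattice).
#' @param inner_folds Number of inner folds (default 5; must be at least 2
#'   and no larger than the smaller class count).
#' @param seed Integer seed for the fold draw.
#' @return An object of class `ai_grid`: a list with `C`, `gamma`, and
#'   `cv_table` (a tibble with one row per pair: `c_exponent`,
#'   `gamma_exponent`, `C`, `gamma`, `accuracy`).
#' @export
grid_search <- function(x, labels = NULL, grid = grid_spec(),
                        inner_folds = 5, seed = 1) {
  inp <- resolve_training_input(x, labels)
  stopifnot(inherits(grid, "grid_spec"))
  if (inner_folds < 2) {
    abort("`inner_folds` must be at least 2", class = "inosine_invalid_input")
  }
  folds <- make_stratified_folds(inp$labels, inner_folds, seed)
  pairs <- tidyr::expand_grid(c_exponent = grid$c_exponents,
                              gamma_exponent = grid$gamma_exponents)
  pairs$C <- grid$base^pairs$c_exponent
  pairs$gamma <- grid$base^pairs$gamma_exponent
  splits <- lapply(seq_len(inner_folds), function(f) {
    list(train = which(folds != f), test = which(folds == f))
  })
  acc <- purrr::map2_dbl(pairs$C, pairs$gamma, function(C, gamma) {
    correct <- 0L
    for (s in splits) {
      fit <- e1071::svm(inp$features[s$train, , drop = FALSE],
                        inp$labels[s$train], type = "C-classification",
                        kernel = "radial", cost = C, gamma = gamma,
                        scale = FALSE)
      pred <- stats::predict(fit, inp$features[s$test, , drop = FALSE])
      correct <- correct + sum(pred == inp$labels[s$test])
    }
    correct / length(inp$labels)
  })
  pairs$accuracy <- acc
  best <- pairs[order(-pairs$accuracy, pairs$C, pairs$gamma), ][1, ]
  structure(
    list(C = best$C, gamma = best$gamma, best_accuracy = best$accuracy,
         cv_table = pairs, inner_folds = inner_folds, seed = seed),
    class = "ai_grid"
  )
}

#' @export
print.ai_grid <- function(x, ...) {
  cat(sprintf(
    "Grid search over %d (C, gamma) pairs (%d-fold inner CV)\n",
    nrow(x$cv_table), x$inner_folds))
  cat(sprintf("  best: C = 2^%d, gamma = 2^%d (accuracy %.4f)\n",
              round(log2(x$C)), round(log2(x$gamma)), x$best_accuracy))
  invisible(x)
}

#' Save or load a trained model
#'
#' The model file is a self-describing archive carrying the SVM parameters,
#' the window half-width xi, the feature dimension, training metadata, and a
#' format-version string that is checked on load.
#'
#' @param model An `ai_svm` object.
#' @param path File path.
#' @return `save_model()` returns the path invisibly; `load_model()` returns
#'   the `ai_svm` object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ai_svm"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("Cannot read model file ", path, ": ", conditionMessage(e)),
          class = "inosine_io_error")
  })
  if (!is.list(obj) || is.null(obj$version)) {
    abort("Not a model file (no format version found)",
          class = "inosine_io_error")
  }
  if (!identical(obj$version, MODEL_FORMAT_VERSION)) {
    abort(paste0("Unsupported model format version \"", obj$version,
                 "\"; this build reads \"", MODEL_FORMAT_VERSION, "\""),
          class = "inosine_io_error")
  }
  structure(obj, class = "ai_svm")
}
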