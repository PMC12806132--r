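#' Stratified train/test split
#'
#' Splits sample ids class by class so the training fraction preserves
#' class proportions to within one sample; every class contributes at
#' least one sample to each partition. Deterministic for a fixed seed.
#'
#' @param sample_ids Character vector.
#' @param labels Class labels aligned with `sample_ids`.
#' @param train_fraction In `(0, 1)`; default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(sample_ids, labels, train_fraction = 0.8,
                             seed = 1) {
  stopifnot(length(sample_ids) == length(labels),
            train_fraction > 0, train_fraction < 1)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("class with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  train <- character(0)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      ids <- sample_ids[labels == cl]
      n <- length(ids)
      n_train <- round(train_fraction * n)
      n_train <- max(1L, min(n - 1L, n_train))
      train <- c(train, sample(ids, n_train))
    }
  })
  list(train = sort(train), test = sort(setdiff(sample_ids, train)))
}

#' Default random-forest hyperparameter grid
#'
#' Conventional coverage of the named tuning dimensions (tree count,
#' depth, feature subsampling, leaf/split minima). Tests and examples
#' use reduced grids; this full grid is the recommended production
#' default.
#'
#' @return data.frame, one row per grid point, scanned in row order.
#' @export
default_rf_grid <- function() {
  expand.grid(n_trees = c(100, 300, 500),
              max_depth = c(Inf, 10, 30),
              mtry = c("sqrt", "log2"),
              min_leaf = c(1, 3),
              min_split = c(2, 5),
              stringsAsFactors = FALSE)
}

stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Fit one omic layer's classifier with grid-search CV
#'
#' Standardises features (training mean/sd; constant features pass
#' through untouched), evaluates every grid point by mean stratified
#' cross-validated accuracy, picks the best (ties broken by grid
#' order), and refits on the full training data. No feature selection
#' is applied beforehand.
#'
#' @param X Samples x features matrix (or an `omic_matrix`, which is
#'   features x samples and gets transposed).
#' @param y Training labels.
#' @param layer Layer tag stored on the model (default from `X` when it
#'   is an `omic_matrix`).
#' @param grid Hyperparameter data.frame as in [default_rf_grid()]
#'   (subset of columns allowed).
#' @param cv_folds Stratified CV folds (default 5).
#' @param seed Integer seed (threads split, forests).
#' @param standardize Standardise features (default `TRUE`).
#' @return A `layer_model`: `fit` (`rf_model`), `layer`, `classes`,
#'   `hyperparameters` (chosen point), `cv_accuracy`, `scaling`.
#' @export
fit_layer <- function(X, y, layer = NULL, grid = NULL, cv_folds = 5,
                      seed = 1, standardize = TRUE) {
  if (inherits(X, "omic_matrix")) {
    layer <- layer %||% omic_layer(X)
    X <- t(unclass(X))
  }
  X <- as.matrix(X)
  layer <- layer %||% "layer"
  y <- as.factor(y)
  if (is.null(grid)) {
    grid <- data.frame(n_trees = 100, stringsAsFactors = FALSE)
  }
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  scaling <- NULL
  if (standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
    scaling <- list(center = mu, scale = sdv)
  }
  grid_args <- function(row) {
    args <- as.list(grid[row, , drop = FALSE])
    args <- lapply(args, function(v) if (is.factor(v)) as.character(v) else v)
    args[intersect(names(args),
                   c("n_trees", "mtry", "max_depth", "min_split",
                     "min_leaf"))]
  }
  best_row <- 1L
  best_acc <- -Inf
  cv_needed <- nrow(grid) > 1
  if (cv_needed) {
    folds <- stratified_folds(y, cv_folds, seed)
    for (g in seq_len(nrow(grid))) {
      args <- grid_args(g)
      accs <- vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f; te <- !tr
        if (!any(te) || length(unique(y[tr])) < nlevels(y)) return(NA_real_)
        m <- do.call(rf_fit, c(list(X = X[tr, , drop = FALSE], y = y[tr],
                                    seed = seed + f), args))
        pr <- rf_predict_proba(m, X[te, , drop = FALSE])
        mean(m$classes[max.col(pr, ties.method = "first")] ==
               as.character(y[te]))
      }, numeric(1))
      acc <- mean(accs, na.rm = TRUE)
      if (acc > best_acc + 1e-12) {  # strict: first grid point wins ties
        best_acc <- acc
        best_row <- g
      }
    }
  }
  args <- grid_args(best_row)
  fit <- do.call(rf_fit, c(list(X = X, y = y, seed = seed), args))
  structure(list(
    fit = fit,
    layer = layer,
    classes = fit$classes,
    hyperparameters = args,
    cv_accuracy = if (cv_needed) best_acc else NA_real_,
    scaling = scaling
  ), class = "layer_model")
}

#' Class probabilities from a fitted layer model
#'
#' @param model A `layer_model`.
#' @param X New samples x features matrix (or features x samples
#'   `omic_matrix`).
#' @return Matrix samples x classes.
#' @export
predict_layer <- function(model, X) {
  if (inherits(X, "omic_matrix")) X <- t(unclass(X))
  X <- as.matrix(X)
  if (!is.null(model$scaling)) {
    X <- align_features(X, names(model$scaling$center))
    X <- sweep(sweep(X, 2, model$scaling$center, "-"),
               2, model$scaling$scale, "/")
  }
  if (inherits(model$fit, "rf_model")) {
    rf_predict_proba(model$fit, X)
  } else {
    svm_predict_proba(model$fit, X)
  }
}

#' Combine per-layer classifiers into a soft-voting ensemble
#'
#' @param layer_models List of `layer_model`s sharing one class set.
#' @param weights Nonnegative per-layer weights; normalised to sum to
#'   1. Default uniform.
#' @return An `ensemble_model`.
#' @export
ensemble_model <- function(layer_models, weights = NULL) {
  stopifnot(length(layer_models) >= 1)
  classes <- layer_models[[1]]$classes
  for (m in layer_models) {
    if (!identical(m$classes, classes)) {
      stop("all layer models must share one class set", call. = FALSE)
    }
  }
  if (is.null(weights)) weights <- rep(1, length(layer_models))
  if (length(weights) != length(layer_models) || any(weights < 0) ||
      sum(weights) == 0) {
    stop("weights must be nonnegative, one per layer, not all zero",
         call. = FALSE)
  }
  names(layer_models) <- vapply(layer_models, function(m) m$layer, "")
  structure(list(layer_models = layer_models,
                 weights = weights / sum(weights),
                 classes = classes),
            class = "ensemble_model")
}

#' Soft-voting ensemble probabilities
#'
#' Weighted average of per-layer class probabilities:
#' `P(k) = sum_m w_m P_m(k)` with the simplex-normalised layer weights
#' (uniform by default). The predicted label is the argmax, ties broken
#' by class order.
#'
#' @param ensemble An `ensemble_model`.
#' @param layer_data Named list (by layer tag) of per-layer feature
#'   matrices covering the same samples, or of precomputed probability
#'   matrices (`samples x classes`). Every layer must be present.
#' @return List with `probabilities` (samples x classes, rows sum to 1)
#'   and `labels` (predicted classes).
#' @export
vote <- function(ensemble, layer_data) {
  lm <- ensemble$layer_models
  miss <- setdiff(names(lm), names(layer_data))
  if (length(miss)) {
    stop("missing data for layer(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  probs <- NULL
  for (i in seq_along(lm)) {
    tag <- names(lm)[i]
    d <- layer_data[[tag]]
    p <- if (is.matrix(d) && identical(colnames(d), ensemble$classes) &&
             !inherits(d, "omic_matrix")) d else predict_layer(lm[[i]], d)
    contrib <- ensemble$weights[i] * p
    probs <- if (is.null(probs)) contrib else probs + contrib
  }
  labels <- ensemble$classes[max.col(probs, ties.method = "first")]
  list(probabilities = probs, labels = labels)
}

#' Classification performance report
#'
#' Per-class precision, recall and F1 (zero-division reported as 0 and
#' flagged), overall accuracy, the confusion matrix, and one-vs-rest
#' ROC curves with AUC computed from the class probabilities.
#'
#' @param probabilities Samples x classes probability matrix.
#' @param truth True labels.
#' @param classes Class order (default: probability column names).
#' @return An `eval_report` list: `accuracy`, `per_class` (data.frame
#'   with precision/recall/F1/AUC and zero-division flags),
#'   `confusion`, `roc` (per-class data.frame of FPR/TPR points),
#'   `macro_f1`.
#' @export
evaluate <- function(probabilities, truth, classes = NULL) {
  classes <- classes %||% colnames(probabilities)
  truth <- as.character(truth)
  unseen <- setdiff(unique(truth), classes)
  if (length(unseen)) {
    stop("test labels contain unseen class(es): ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  pred <- classes[max.col(probabilities, ties.method = "first")]
  confusion <- table(factor(truth, classes), factor(pred, classes),
                     dnn = c("truth", "predicted"))
  acc <- mean(pred == truth)
  per_class <- do.call(rbind, lapply(classes, function(k) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    prec_zero <- (tp + fp) == 0
    rec_zero <- (tp + fn) == 0
    precision <- if (prec_zero) 0 else tp / (tp + fp)
    recall <- if (rec_zero) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0
          else 2 * precision * recall / (precision + recall)
    data.frame(class = k, precision = precision, recall = recall, f1 = f1,
               auc = roc_auc(probabilities[, k], truth == k),
               zero_division = prec_zero || rec_zero,
               stringsAsFactors = FALSE)
  }))
  roc <- lapply(stats::setNames(classes, classes), function(k) {
    roc_points(probabilities[, k], truth == k)
  })
  structure(list(accuracy = acc, per_class = per_class,
                 confusion = confusion, roc = roc,
                 macro_f1 = mean(per_class$f1)),
            class = "eval_report")
}

# one-vs-rest AUC via the rank (Mann-Whitney) formulation; mid-ranks
# handle tied scores. NA when a class is absent from the truth.
roc_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  pos <- positive[ord]
  tpr <- c(0, cumsum(pos) / max(1, sum(pos)))
  fpr <- c(0, cumsum(!pos) / max(1, sum(!pos)))
  data.frame(fpr = fpr, tpr = tpr)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f, macro-F1 %.4f\n",
              x$accuracy, x$macro_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Rank features by mean absolute SHAP value
#'
#' Computes per-sample SHAP attributions on an evaluation set
#' (conventionally the held-out test partition), averages their
#' absolute values over samples and — for multi-class models — over
#' classes, and flags features whose mean exceeds a small threshold
#' (1e-4 by convention) as selected markers.
#'
#' @param model A `layer_model` or `rf_model`.
#' @param X Evaluation samples x features matrix (or features x samples
#'   `omic_matrix`).
#' @param threshold Selection threshold on mean |SHAP| (default 1e-4).
#' @return A `shap_ranking` data.frame: `feature_id`, `mean_abs_shap`,
#'   `selected`, sorted decreasing.
#' @export
shap_rank <- function(model, X, threshold = 1e-4) {
  if (inherits(X, "omic_matrix")) X <- t(unclass(X))
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty evaluation set", call. = FALSE)
  rf <- model
  if (inherits(model, "layer_model")) {
    if (!is.null(model$scaling)) {
      X <- align_features(X, names(model$scaling$center))
      X <- sweep(sweep(X, 2, model$scaling$center, "-"),
                 2, model$scaling$scale, "/")
    }
    rf <- model$fit
  }
  sh <- rf_shap(rf, X)
  mean_abs <- Reduce(`+`, lapply(sh$phi, function(m) colMeans(abs(m)))) /
    length(sh$phi)
  out <- data.frame(feature_id = names(mean_abs),
                    mean_abs_shap = unname(mean_abs),
                    stringsAsFactors = FALSE)
  out$selected <- out$mean_abs_shap > threshold
  out <- out[order(-out$mean_abs_shap, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shap_ranking", "data.frame")
  out
}
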