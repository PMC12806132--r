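#' Fit a random forest classifier
#'
#' Bagged CART trees with Gini splitting and per-node feature
#' subsampling. Trees average their leaf class-frequency vectors at
#' prediction time, so the forest outputs calibratable class
#' probabilities. Fitting is driven by an internal deterministic PRNG:
#' the same seed gives a bit-identical forest independent of R's global
#' RNG state.
#'
#' @param X Numeric samples x features matrix (column names = feature
#'   ids).
#' @param y Class labels (factor or character).
#' @param n_trees Number of trees (default 100).
#' @param mtry Features tried per split: `"sqrt"` (default), `"log2"`,
#'   or an integer.
#' @param max_depth Maximum tree depth (`Inf`/`NULL` = unlimited).
#' @param min_split Minimum node size to attempt a split (default 2).
#' @param min_leaf Minimum samples per leaf (default 1).
#' @param seed Integer seed.
#' @return An `rf_model` with elements `trees`, `classes`,
#'   `feature_ids`, `hyperparameters`.
#' @export
rf_fit <- function(X, y, n_trees = 100, mtry = "sqrt", max_depth = Inf,
                   min_split = 2, min_leaf = 1, seed = 1) {
  X <- as.matrix(X)
  y <- as.factor(y)
  classes <- levels(y)
  if (nrow(X) != length(y)) stop("X rows must match length(y)", call. = FALSE)
  p <- ncol(X)
  mtry_n <- resolve_mtry(mtry, p)
  md <- if (is.null(max_depth) || !is.finite(max_depth)) 0L
        else as.integer(max_depth)
  trees <- cpp_rf_fit(X, as.integer(y) - 1L, length(classes),
                      as.integer(n_trees), as.integer(mtry_n), md,
                      as.integer(min_split), as.integer(min_leaf),
                      as.numeric(seed))
  structure(list(
    trees = trees,
    classes = classes,
    feature_ids = colnames(X),
    hyperparameters = list(n_trees = n_trees, mtry = mtry,
                           max_depth = max_depth, min_split = min_split,
                           min_leaf = min_leaf, seed = seed)
  ), class = "rf_model")
}

resolve_mtry <- function(mtry, p) {
  if (is.character(mtry)) {
    switch(mtry,
           sqrt = max(1L, floor(sqrt(p))),
           log2 = max(1L, floor(log2(p))),
           all = p,
           stop("unknown mtry spec: ", mtry, call. = FALSE))
  } else {
    max(1L, min(as.integer(mtry), p))
  }
}

#' Class probabilities from a random forest
#'
#' @param model An `rf_model`.
#' @param X Samples x features matrix with the training feature columns.
#' @return Numeric matrix samples x classes; rows sum to 1.
#' @export
rf_predict_proba <- function(model, X) {
  X <- align_features(X, model$feature_ids)
  probs <- cpp_rf_predict(model$trees, X, length(model$classes))
  dimnames(probs) <- list(rownames(X), model$classes)
  probs
}

align_features <- function(X, feature_ids) {
  X <- as.matrix(X)
  if (!is.null(feature_ids) && !is.null(colnames(X))) {
    miss <- setdiff(feature_ids, colnames(X))
    if (length(miss)) {
      stop("prediction data lacks feature(s): ",
           paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
    }
    X <- X[, feature_ids, drop = FALSE]
  }
  X
}

#' Per-sample SHAP attributions from a random forest
#'
#' Path-dependent TreeSHAP: feature attributions are exact Shapley
#' values of the tree-structured conditional expectation, computed in
#' polynomial time; per sample and class, attributions plus the base
#' value reproduce the forest's probability output (local accuracy).
#'
#' @param model An `rf_model`.
#' @param X Samples x features matrix.
#' @return List with `phi` (list of samples x features matrices, one
#'   per class) and `base` (named per-class expected value).
#' @export
rf_shap <- function(model, X) {
  X <- align_features(X, model$feature_ids)
  if (nrow(X) == 0) stop("empty evaluation set", call. = FALSE)
  out <- cpp_rf_shap(model$trees, X, length(model$classes))
  names(out$phi) <- model$classes
  for (k in seq_along(out$phi)) {
    dimnames(out$phi[[k]]) <- list(rownames(X), model$feature_ids)
  }
  names(out$base) <- model$classes
  out
}
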