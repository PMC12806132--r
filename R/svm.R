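#' Linear support-vector-machine baseline
#'
#' A margin-based comparison classifier: one-vs-rest linear SVMs with
#' squared-hinge loss and L2 regularisation, trained by deterministic
#' full-batch gradient descent on standardised features, with
#' Platt-style sigmoid calibration of the decision values so the model
#' emits class probabilities comparable to the forest's. Used for
#' baseline comparison reports only; kernels are out of scope.
#'
#' @param X Samples x features matrix (or features x samples
#'   `omic_matrix`).
#' @param y Class labels.
#' @param layer Layer tag for the report.
#' @param grid data.frame with column `cost` (inverse regularisation);
#'   multiple rows are scanned by stratified CV accuracy like
#'   [fit_layer()].
#' @param cv_folds Stratified CV folds when the grid has several rows.
#' @param seed Integer seed (fold assignment only; optimisation is
#'   deterministic).
#' @return A `layer_model` whose `fit` is an `svm_model`.
#' @export
svm_baseline <- function(X, y, layer = "baseline",
                         grid = data.frame(cost = 1), cv_folds = 3,
                         seed = 1) {
  if (inherits(X, "omic_matrix")) {
    layer <- omic_layer(X)
    X <- t(unclass(X))
  }
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  best_row <- 1L
  if (nrow(grid) > 1) {
    folds <- stratified_folds(y, cv_folds, seed)
    best_acc <- -Inf
    for (g in seq_len(nrow(grid))) {
      accs <- vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f
        if (length(unique(y[tr])) < nlevels(y)) return(NA_real_)
        m <- svm_fit_core(Xs[tr, , drop = FALSE], y[tr], grid$cost[g])
        pr <- svm_predict_proba(m, Xs[!tr, , drop = FALSE])
        mean(m$classes[max.col(pr, ties.method = "first")] ==
               as.character(y[!tr]))
      }, numeric(1))
      acc <- mean(accs, na.rm = TRUE)
      if (acc > best_acc + 1e-12) { best_acc <- acc; best_row <- g }
    }
  }
  fit <- svm_fit_core(Xs, y, grid$cost[best_row])
  structure(list(fit = fit, layer = layer, classes = fit$classes,
                 hyperparameters = list(cost = grid$cost[best_row]),
                 cv_accuracy = NA_real_,
                 scaling = list(center = mu, scale = sdv)),
            class = "layer_model")
}

svm_fit_core <- function(X, y, cost = 1, n_iter = 300, lr = 0.1) {
  classes <- levels(y)
  n <- nrow(X); p <- ncol(X)
  lambda <- 1 / (cost * n)
  models <- lapply(classes, function(k) {
    t_ <- ifelse(y == k, 1, -1)
    w <- numeric(p); b <- 0
    for (it in seq_len(n_iter)) {
      f <- drop(X %*% w) + b
      margin <- 1 - t_ * f
      active <- margin > 0
      # squared hinge: grad = -2 t (1 - t f)_+ x
      gw <- -2 * drop(crossprod(X[active, , drop = FALSE],
                                (t_ * margin)[active])) / n + 2 * lambda * w
      gb <- -2 * sum((t_ * margin)[active]) / n
      w <- w - lr * gw
      b <- b - lr * gb
    }
    f <- drop(X %*% w) + b
    ab <- platt_fit(f, t_ == 1)
    list(w = w, b = b, platt = ab)
  })
  names(models) <- classes
  structure(list(models = models, classes = classes,
                 feature_ids = colnames(X)),
            class = "svm_model")
}

# Platt scaling: logistic fit of P(positive | decision value) by IRLS
platt_fit <- function(f, pos, n_iter = 50) {
  t_ <- ifelse(pos, (sum(pos) + 1) / (sum(pos) + 2), 1 / (sum(!pos) + 2))
  a <- 0; b <- 0
  for (it in seq_len(n_iter)) {
    z <- a * f + b
    p <- 1 / (1 + exp(-z))
    g <- c(sum((p - t_) * f), sum(p - t_))
    w <- pmax(p * (1 - p), 1e-10)
    H <- rbind(c(sum(w * f * f) + 1e-8, sum(w * f)),
               c(sum(w * f), sum(w) + 1e-8))
    step <- solve(H, g)
    a <- a - step[1]; b <- b - step[2]
    if (max(abs(step)) < 1e-10) break
  }
  c(a = a, b = b)
}

svm_predict_proba <- function(model, X) {
  X <- align_features(X, model$feature_ids)
  raw <- vapply(model$models, function(m) {
    f <- drop(X %*% m$w) + m$b
    1 / (1 + exp(-(m$platt["a"] * f + m$platt["b"])))
  }, numeric(nrow(X)))
  raw <- matrix(raw, nrow = nrow(X),
                dimnames = list(rownames(X), model$classes))
  sweep(raw, 1, pmax(rowSums(raw), 1e-12), "/")
}
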