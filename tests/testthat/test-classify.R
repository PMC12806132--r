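multiomic_fixture <- function(seed = 1, n_per_class = 20, shift = 2.5) {
  with_seed_local(seed, {
    n <- 2 * n_per_class
    ids <- sprintf("s%02d", 1:n)
    y <- stats::setNames(rep(c("A", "B"), each = n_per_class), ids)
    mk <- function(p, informative) {
      X <- matrix(stats::rnorm(n * p), n, p,
                  dimnames = list(ids, paste0("f", 1:p)))
      X[y == "B", seq_len(informative)] <-
        X[y == "B", seq_len(informative)] + shift
      X
    }
    list(ids = ids, y = y,
         layers = list(L1 = mk(15, 3), L2 = mk(10, 2)))
  })
}

test_that("split_train_test stratifies exactly and deterministically", {
  ids <- paste0("s", 1:20)
  y <- rep(c("A", "B"), each = 10)
  sp <- split_train_test(ids, y, 0.8, seed = 3)
  expect_length(sp$train, 16)
  expect_length(sp$test, 4)
  expect_equal(sum(sp$train %in% ids[1:10]), 8)  # 8 + 8 train, 2 + 2 test
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_train_test(ids, y, 0.8, seed = 3))
  expect_false(identical(sp, split_train_test(ids, y, 0.8, seed = 4)))
  expect_error(split_train_test(c("a", "b", "c"), c("A", "A", "B"), 0.8, 1),
               "fewer than 2.*B")
})

test_that("minority classes always reach both partitions", {
  ids <- paste0("s", 1:12)
  y <- c(rep("A", 9), rep("B", 3))
  for (seed in 1:10) {
    sp <- split_train_test(ids, y, 0.8, seed = seed)
    expect_gte(sum(sp$test %in% ids[10:12]), 1)
    expect_gte(sum(sp$train %in% ids[10:12]), 1)
  }
})

test_that("fit_layer honours the grid contract", {
  d <- multiomic_fixture()
  expect_error(fit_layer(d$layers$L1, d$y, grid = data.frame()),
               "empty.*grid")
  # degenerate one-point grid: that point is chosen without CV
  f1 <- fit_layer(d$layers$L1, d$y,
                  grid = data.frame(n_trees = 30), seed = 2)
  expect_equal(f1$hyperparameters$n_trees, 30)
  expect_true(is.na(f1$cv_accuracy))
  # equal-scoring grid points: first listed wins (identical settings twice)
  f2 <- fit_layer(d$layers$L1, d$y, cv_folds = 3, seed = 2,
                  grid = data.frame(n_trees = c(25, 25), mtry = "sqrt",
                                    stringsAsFactors = FALSE))
  expect_equal(f2$hyperparameters$n_trees, 25)
  # separable blobs classify nearly perfectly under CV
  f3 <- fit_layer(d$layers$L1, d$y, cv_folds = 3, seed = 2,
                  grid = data.frame(n_trees = c(20, 40)))
  expect_gt(f3$cv_accuracy, 0.95)
})

test_that("vote is the weighted probability mean with tie-safe argmax", {
  p1 <- matrix(c(0.6, 0.4), 1, dimnames = list("s", c("A", "B")))
  p2 <- matrix(c(0.8, 0.2), 1, dimnames = list("s", c("A", "B")))
  fake_layer <- function(tag) {
    structure(list(layer = tag, classes = c("A", "B"), fit = NULL,
                   scaling = NULL), class = "layer_model")
  }
  ens <- ensemble_model(list(fake_layer("x"), fake_layer("y")))
  v <- vote(ens, list(x = p1, y = p2))
  expect_equal(unname(v$probabilities), matrix(c(0.7, 0.3), 1))
  expect_equal(v$labels, "A")
  # degenerate weights pick one layer exactly
  ens10 <- ensemble_model(list(fake_layer("x"), fake_layer("y")),
                          weights = c(1, 0))
  expect_equal(vote(ens10, list(x = p1, y = p2))$probabilities, p1)
  # single layer: identity
  ens1 <- ensemble_model(list(fake_layer("x")))
  expect_equal(vote(ens1, list(x = p1))$probabilities, p1)
  # missing layer is an error, not silent imputation
  expect_error(vote(ens, list(x = p1)), "missing data.*y")
  expect_error(ensemble_model(list(fake_layer("x")), weights = c(-1)),
               "nonnegative")
})

test_that("vote probabilities stay on the simplex for random weights", {
  d <- multiomic_fixture(seed = 4)
  sp <- split_train_test(d$ids, d$y, 0.8, seed = 4)
  fits <- lapply(names(d$layers), function(tag)
    fit_layer(d$layers[[tag]][sp$train, ], d$y[sp$train], layer = tag,
              grid = data.frame(n_trees = 20), seed = 4))
  test_data <- lapply(d$layers, function(X) X[sp$test, ])
  withr::with_seed(6, {
    for (i in 1:10) {
      w <- stats::runif(2)
      ens <- ensemble_model(fits, weights = w)
      v <- vote(ens, test_data)
      expect_equal(unname(rowSums(v$probabilities)),
                   rep(1, length(sp$test)), tolerance = 1e-9)
    }
  })
  # uniform weights equal the unweighted mean of layer probabilities
  ens_u <- ensemble_model(fits)
  v_u <- vote(ens_u, test_data)
  manual <- (predict_layer(fits[[1]], test_data$L1) +
               predict_layer(fits[[2]], test_data$L2)) / 2
  expect_equal(v_u$probabilities, manual, tolerance = 1e-12)
})

test_that("evaluate reproduces hand-computed metrics", {
  # TP = 8, FP = 2, FN = 4 for class 'pos' on 20 samples
  truth <- c(rep("pos", 12), rep("neg", 8))
  pred <- c(rep("pos", 8), rep("neg", 4), rep("pos", 2), rep("neg", 6))
  probs <- cbind(neg = as.numeric(pred == "neg"),
                 pos = as.numeric(pred == "pos"))
  rep_ <- evaluate(probs, truth)
  pos <- rep_$per_class[rep_$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.8)
  expect_equal(pos$recall, 8 / 12, tolerance = 1e-4)
  expect_equal(pos$f1, 2 * 0.8 * (8 / 12) / (0.8 + 8 / 12), tolerance = 1e-4)
  expect_equal(rep_$accuracy, 14 / 20)
  expect_equal(sum(rep_$confusion), 20)

  # perfect predictor
  probs2 <- cbind(neg = as.numeric(truth == "neg"),
                  pos = as.numeric(truth == "pos"))
  rep2 <- evaluate(probs2, truth)
  expect_equal(rep2$accuracy, 1)
  expect_true(all(rep2$per_class[, c("precision", "recall", "f1", "auc")] == 1))

  # uninformative constant probabilities: AUC 0.5 on balanced data
  truth3 <- rep(c("a", "b"), each = 10)
  probs3 <- matrix(0.5, 20, 2, dimnames = list(NULL, c("a", "b")))
  rep3 <- evaluate(probs3, truth3)
  expect_equal(rep3$per_class$auc, c(0.5, 0.5))

  # zero-division flagged, not NaN; unseen classes rejected
  probs4 <- cbind(a = rep(1, 4), b = rep(0, 4))
  rep4 <- evaluate(probs4, rep("a", 4))
  expect_true(rep4$per_class$zero_division[2])
  expect_equal(rep4$per_class$f1[2], 0)
  expect_error(evaluate(probs4, c("a", "a", "c", "a")), "unseen")
})

test_that("shap_rank applies the threshold rule and finds planted markers", {
  d <- multiomic_fixture(seed = 8)
  sp <- split_train_test(d$ids, d$y, 0.8, seed = 8)
  f <- fit_layer(d$layers$L1[sp$train, ], d$y[sp$train], layer = "L1",
                 grid = data.frame(n_trees = 40), seed = 8)
  sr <- shap_rank(f, d$layers$L1[sp$test, ])
  expect_s3_class(sr, "shap_ranking")
  expect_identical(sr$selected, sr$mean_abs_shap > 1e-4)
  expect_false(is.unsorted(rev(sr$mean_abs_shap)))
  # the 3 informative features dominate the top of the ranking
  expect_gte(sum(paste0("f", 1:3) %in% sr$feature_id[1:6]), 2)
  expect_error(shap_rank(f, d$layers$L1[integer(0), ]), "empty")
})

test_that("svm baseline separates blobs and emits calibrated layers", {
  # large held-out evaluation set so the accuracy bound is not at the
  # mercy of a handful of test points
  blob <- function(n) {
    X <- matrix(stats::rnorm(n * 15), n, 15,
                dimnames = list(NULL, paste0("f", 1:15)))
    y <- rep(c("A", "B"), each = n / 2)
    X[y == "B", 1:3] <- X[y == "B", 1:3] + 3
    list(X = X, y = y)
  }
  with_seed_local(10, {
    tr <- blob(60)
    te <- blob(200)
  })
  f <- svm_baseline(tr$X, tr$y, seed = 10)
  p <- predict_layer(f, te$X)
  expect_equal(unname(rowSums(p)), rep(1, 200), tolerance = 1e-9)
  expect_gt(evaluate(p, te$y)$accuracy, 0.95)
  # degenerate single-feature data still runs
  f1 <- svm_baseline(tr$X[, 1, drop = FALSE], tr$y, seed = 1)
  expect_equal(ncol(predict_layer(f1, te$X[, 1, drop = FALSE])), 2)
})
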