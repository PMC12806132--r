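lung_metadata <- function() {
  # fully populated label battery: N plus AD/SC across stages, SCLC
  rows <- list()
  add <- function(cond, sub, stg, n) {
    start <- length(rows)
    for (i in seq_len(n)) {
      rows[[start + i]] <<- data.frame(
        sample_id = sprintf("%s_%s_%s_%d", cond, sub,
                            if (is.na(stg)) "NA" else stg, i),
        condition = cond, subtype = sub, stage = stg,
        stringsAsFactors = FALSE)
    }
  }
  add("N", "N", NA_character_, 6)
  for (s in c("S1", "S2", "S3", "S4")) {
    add("C", "AD", s, 4)
    add("C", "SC", s, 4)
  }
  add("C", "SCLC", NA_character_, 5)
  do.call(rbind, rows)
}

test_that("lung scheme emits the full 36-comparison battery", {
  md <- lung_metadata()
  groups <- build_groups(md, "lung36")
  expect_length(groups, 36)
  names36 <- vapply(groups, function(g) g$name, "")
  expect_true(all(c("C-N", "SCLC-NSCLC", "N-AD-SC", "AD-N", "SC-N",
                    "SC-AD", "AD-stages", "SC-stages", "AD-S2-S1",
                    "SC-S4-S3", "AD-S1-N", "AD-SC-S2", "S1-N", "S4-N")
                  %in% names36))
  g <- groups[[which(names36 == "N-AD-SC")]]
  expect_equal(g$test_kind, "k_sample")
  expect_equal(groups[[1]]$test_kind, "two_sample")
})

test_that("empty comparison groups are dropped with a warning", {
  md <- lung_metadata()
  md <- md[md$subtype %in% c("N", "AD"), ]
  expect_warning(groups <- build_groups(md, "lung36"), "dropped")
  nm <- vapply(groups, function(g) g$name, "")
  expect_false(any(nm %in% c("SC-N", "SC-AD", "SCLC-NSCLC")))
  expect_true("AD-N" %in% nm)
})

test_that("pancreas scheme yields N-C and N-S1", {
  md <- data.frame(
    sample_id = paste0("s", 1:12),
    condition = rep(c("N", "C"), each = 6),
    subtype = rep(c("N", "C"), each = 6),
    stage = c(rep(NA, 6), "S1", "S1", "S1", "S2", "S2", "S3"),
    stringsAsFactors = FALSE)
  groups <- build_groups(md, "pancreas2")
  expect_equal(vapply(groups, function(g) g$name, ""), c("N-C", "N-S1"))
  expect_length(groups[[2]]$member_sets$S1, 3)
})

test_that("custom scheme builds one group over the label column", {
  md <- data.frame(sample_id = paste0("s", 1:9),
                   condition = rep(c("a", "b", "c"), 3),
                   stringsAsFactors = FALSE)
  g <- build_groups(md, "custom")
  expect_length(g, 1)
  expect_equal(g[[1]]$test_kind, "k_sample")
  expect_error(comparison_group("x", list(a = "s1")), "at least 2")
  expect_error(comparison_group("x", list(a = "s1", b = "s1")),
               "overlapping")
})

test_that("Mann-Whitney exact p equals full enumeration", {
  expect_equal(rank_test(comparison_group("t", list(a = paste0("a", 1:3),
                                                    b = paste0("b", 1:3))),
                         stats::setNames(1:6, c(paste0("a", 1:3),
                                                paste0("b", 1:3))))$p_raw,
               0.1)
  withr::with_seed(99, {
    for (i in 1:40) {
      n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
      x <- round(stats::rnorm(n1), 1)   # rounding forces occasional ties
      y <- round(stats::rnorm(n2), 1)
      ids <- c(paste0("x", seq_len(n1)), paste0("y", seq_len(n2)))
      g <- comparison_group("t", list(a = ids[seq_len(n1)],
                                      b = ids[-seq_len(n1)]))
      got <- rank_test(g, stats::setNames(c(x, y), ids))
      expect_equal(got$p_raw, oracle_mw_exact(x, y))
    }
  })
})

test_that("identical member sets give p = 1; approximation matches base R", {
  ids <- c(paste0("a", 1:3), paste0("b", 1:3))
  g <- comparison_group("t", list(a = ids[1:3], b = ids[4:6]))
  res <- rank_test(g, stats::setNames(c(1, 2, 3, 1, 2, 3), ids))
  expect_equal(res$p_raw, 1)
  expect_false(res$degenerate)  # values vary, only the split is balanced
  res2 <- rank_test(g, stats::setNames(rep(1, 6), ids))
  expect_true(res2$degenerate)

  # large-sample normal approximation tracks stats::wilcox.test
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- stats::rnorm(15); y <- stats::rnorm(18, 0.3)
      ids <- c(paste0("x", 1:15), paste0("y", 1:18))
      g2 <- comparison_group("t", list(a = ids[1:15], b = ids[-(1:15)]))
      got <- rank_test(g2, stats::setNames(c(x, y), ids))
      ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
      expect_equal(got$p_raw, ref$p.value, tolerance = 1e-10)
      expect_equal(got$statistic, unname(ref$statistic))
    }
  })
})

test_that("Kruskal-Wallis matches stats::kruskal.test including ties", {
  withr::with_seed(8, {
    for (i in 1:20) {
      sets <- lapply(1:3, function(j) round(stats::rnorm(6 + j), 1))
      ids <- paste0("s", seq_len(sum(lengths(sets))))
      split_ids <- split(ids, rep(1:3, lengths(sets)))
      g <- comparison_group("t", stats::setNames(split_ids, c("a", "b", "c")))
      got <- rank_test(g, stats::setNames(unlist(sets), ids))
      ref <- stats::kruskal.test(unlist(sets), rep(1:3, lengths(sets)))
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$p_raw, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("bh_adjust equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(21, {
    for (i in 1:200) {
      p <- stats::runif(sample(1:20, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p))
      expect_true(all(adj >= p - 1e-15))
    }
  })
})

test_that("lilliefors test rejects heavy tails and is calibrated", {
  # heavy-tailed alternative: strong rejection in most seeds
  rejected <- vapply(1:10, function(s) {
    x <- with_seed_local(s, stats::rt(500, df = 2))
    lilliefors_test(x, n_mc = 400, seed = s)$p_value < 0.01
  }, logical(1))
  expect_gte(sum(rejected), 9)
  # null calibration: p-values roughly uniform across seeds
  pvals <- vapply(1:120, function(s) {
    x <- with_seed_local(1000 + s, stats::rnorm(100))
    lilliefors_test(x, n_mc = 150, seed = s)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
  # degenerate input flagged
  res <- lilliefors_test(rep(1, 10), n_mc = 100)
  expect_true(res$degenerate)
  expect_lt(res$p_value, 1 / 100)
  expect_error(lilliefors_test(c(1, 2, 3)), "n >= 4")
})

test_that("diff_test excludes zero-variance features and adjusts p", {
  ids <- c(paste0("a", 1:5), paste0("b", 1:5))
  g <- comparison_group("t", list(a = ids[1:5], b = ids[6:10]))
  v <- rbind(shifted = c(1:5, 6:10),
             flat = rep(2, 10),
             noise = c(2, 4, 1, 5, 3, 3, 5, 1, 4, 2))
  colnames(v) <- ids
  d <- diff_test(omic_matrix(v, "JX"), g)
  expect_equal(attr(d, "excluded"), "flat")
  expect_equal(nrow(d), 2)
  expect_true(all(d$p_adj >= d$p_raw - 1e-15))
  expect_equal(attr(d, "layer"), "JX")
  expect_lt(d$p_raw[d$feature_id == "shifted"], 0.01)
})
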