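#' Define a comparison group
#'
#' @param name Display name, e.g. `"C-N"`.
#' @param member_sets Named list of sample-id character vectors (two or
#'   more, disjoint, nonempty).
#' @return A `comparison_group` with `test_kind` `"two_sample"` (exactly
#'   two sets, Mann-Whitney) or `"k_sample"` (Kruskal-Wallis).
#' @export
comparison_group <- function(name, member_sets) {
  if (length(member_sets) < 2) {
    stop("comparison group needs at least 2 member sets", call. = FALSE)
  }
  if (any(lengths(member_sets) == 0)) {
    stop("comparison group '", name, "' has an empty member set",
         call. = FALSE)
  }
  all_ids <- unlist(member_sets)
  if (anyDuplicated(all_ids)) {
    stop("comparison group '", name, "' has overlapping member sets",
         call. = FALSE)
  }
  structure(list(
    name = name,
    member_sets = member_sets,
    test_kind = if (length(member_sets) == 2) "two_sample" else "k_sample"
  ), class = "comparison_group")
}

#' Build comparison groups from sample metadata
#'
#' `metadata` must have columns `sample_id`, `condition` (`N`/`C`), and
#' optionally `subtype` (`AD`, `SC`, `SCLC`, ... ; `N` for normals) and
#' `stage` (`S1`..`S4`, `NA` when unstaged).
#'
#' Schemes:
#' \describe{
#'   \item{`lung36`}{The full lung comparison battery (36 groups when
#'     every label is populated): C-N, SCLC-NSCLC, the three-way
#'     N-AD-SC, AD-N, SC-N, SC-AD; the k-sample across-stage groups
#'     AD-stages and SC-stages; the six stage pairs (2-1, 3-1, 4-1,
#'     3-2, 4-2, 4-3) within AD and within SC; per-stage AD-N, SC-N and
#'     AD-SC; and pooled per-stage S1-N .. S4-N. Groups whose member
#'     sets are empty in the data are dropped with a warning.}
#'   \item{`pancreas2`}{N-C and N-S1.}
#'   \item{`custom`}{One group per distinct value of `custom_column`
#'     (two-sample if two labels, otherwise one k-sample group).}
#' }
#'
#' @param metadata Sample metadata data.frame.
#' @param scheme `"lung36"`, `"pancreas2"` or `"custom"`.
#' @param custom_column Column used by the custom scheme (default
#'   `"condition"`).
#' @return List of `comparison_group` objects.
#' @export
build_groups <- function(metadata,
                         scheme = c("lung36", "pancreas2", "custom"),
                         custom_column = "condition") {
  scheme <- match.arg(scheme)
  md <- metadata
  stopifnot(all(c("sample_id", "condition") %in% names(md)))
  if (!"subtype" %in% names(md)) md$subtype <- md$condition
  if (!"stage" %in% names(md)) md$stage <- NA_character_
  pick <- function(expr_idx) md$sample_id[expr_idx]
  sets <- list()
  add <- function(name, ...) {
    ms <- list(...)
    sets[[length(sets) + 1L]] <<- list(name = name, member_sets = ms)
  }
  if (scheme == "custom") {
    labs <- sort(unique(md[[custom_column]]))
    ms <- lapply(labs, function(l) pick(md[[custom_column]] == l))
    names(ms) <- labs
    g <- comparison_group(paste(labs, collapse = "-"), ms)
    return(list(g))
  }
  is_n <- md$condition == "N"
  is_c <- md$condition == "C"
  if (scheme == "pancreas2") {
    add("N-C", N = pick(is_n), C = pick(is_c))
    add("N-S1", N = pick(is_n), S1 = pick(is_c & md$stage %in% "S1"))
  } else {
    sub <- md$subtype
    stg <- md$stage
    add("C-N", C = pick(is_c), N = pick(is_n))
    add("SCLC-NSCLC",
        SCLC = pick(sub %in% "SCLC"),
        NSCLC = pick(sub %in% c("AD", "SC", "LaC", "NSCLC")))
    add("N-AD-SC", N = pick(is_n), AD = pick(sub %in% "AD"),
        SC = pick(sub %in% "SC"))
    add("AD-N", AD = pick(sub %in% "AD"), N = pick(is_n))
    add("SC-N", SC = pick(sub %in% "SC"), N = pick(is_n))
    add("SC-AD", SC = pick(sub %in% "SC"), AD = pick(sub %in% "AD"))
    stages <- c("S1", "S2", "S3", "S4")
    for (subty in c("AD", "SC")) {
      ms <- lapply(stages, function(s) pick(sub %in% subty & stg %in% s))
      names(ms) <- stages
      ms <- ms[lengths(ms) > 0]
      if (length(ms) >= 2) {
        sets[[length(sets) + 1L]] <- list(
          name = paste0(subty, "-stages"), member_sets = ms)
      } else {
        sets[[length(sets) + 1L]] <- list(
          name = paste0(subty, "-stages"),
          member_sets = lapply(stages, function(s)
            pick(sub %in% subty & stg %in% s)))
        names(sets[[length(sets)]]$member_sets) <- stages
      }
      pairs <- list(c(2, 1), c(3, 1), c(4, 1), c(3, 2), c(4, 2), c(4, 3))
      for (p in pairs) {
        s_hi <- stages[p[1]]; s_lo <- stages[p[2]]
        nm <- paste0(subty, "-", s_hi, "-", s_lo)
        ms <- stats::setNames(
          list(pick(sub %in% subty & stg %in% s_hi),
               pick(sub %in% subty & stg %in% s_lo)), c(s_hi, s_lo))
        sets[[length(sets) + 1L]] <- list(name = nm, member_sets = ms)
      }
    }
    for (s in stages) {
      add(paste0("AD-", s, "-N"),
          AD = pick(sub %in% "AD" & stg %in% s), N = pick(is_n))
      add(paste0("SC-", s, "-N"),
          SC = pick(sub %in% "SC" & stg %in% s), N = pick(is_n))
      add(paste0("AD-SC-", s),
          AD = pick(sub %in% "AD" & stg %in% s),
          SC = pick(sub %in% "SC" & stg %in% s))
      add(paste0(s, "-N"), S = pick(is_c & stg %in% s), N = pick(is_n))
    }
  }
  out <- list()
  dropped <- character(0)
  for (g in sets) {
    ms <- g$member_sets[lengths(g$member_sets) > 0]
    if (length(ms) >= 2) {
      out[[length(out) + 1L]] <- comparison_group(g$name, ms)
    } else {
      dropped <- c(dropped, g$name)
    }
  }
  if (length(dropped)) {
    warning("dropped comparison group(s) with empty member sets: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out
}

#' Lilliefors test of composite normality (Monte-Carlo p-value)
#'
#' Kolmogorov-Smirnov distance between the empirical distribution and a
#' normal with mean/sd estimated from the data; because parameters are
#' estimated, the null distribution of the distance is obtained by
#' seeded Monte-Carlo resampling (each resample re-estimates the
#' parameters).
#'
#' @param x Numeric sample, `n >= 4`.
#' @param n_mc Number of Monte-Carlo null resamples.
#' @param seed Integer seed for the null resamples.
#' @return List with `statistic` (the KS distance), `p_value`, and
#'   `degenerate` (`TRUE` for constant input, where `p_value` is
#'   reported as `1 / (n_mc + 1)`).
#' @export
lilliefors_test <- function(x, n_mc = 1000, seed = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("lilliefors_test needs n >= 4", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p_value = 1 / (n_mc + 1),
                degenerate = TRUE))
  }
  ks_dist <- function(v) {
    z <- sort((v - mean(v)) / stats::sd(v))
    p <- stats::pnorm(z)
    i <- seq_len(length(v))
    max(i / length(v) - p, p - (i - 1) / length(v))
  }
  d_obs <- ks_dist(x)
  d_null <- with_seed(seed, {
    vapply(seq_len(n_mc), function(k) ks_dist(stats::rnorm(n)), numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (n_mc + 1)
  list(statistic = d_obs, p_value = p, degenerate = FALSE)
}

#' Rank-based test between comparison-group member sets
#'
#' Two sets: two-sided Mann-Whitney (Wilcoxon rank-sum) with mid-rank
#' ties; the p-value is exact (full enumeration of group assignments)
#' when the combined sample size is at most `exact_max`, otherwise a
#' normal approximation with continuity and tie correction is used.
#' Three or more sets: Kruskal-Wallis chi-square approximation with tie
#' correction.
#'
#' @param group A `comparison_group`.
#' @param values Named numeric vector (names = sample ids) covering all
#'   members.
#' @param exact_max Combined-n cutover from exact to approximate
#'   Mann-Whitney (default 20).
#' @return List with `statistic` (U or H), `p_raw`, `method`, and
#'   `degenerate` (`TRUE` when all values coincide; then `p_raw = 1`).
#' @export
rank_test <- function(group, values, exact_max = 20) {
  sets <- lapply(group$member_sets, function(ids) {
    miss <- setdiff(ids, names(values))
    if (length(miss)) {
      stop("values missing for sample(s): ",
           paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
    }
    unname(values[ids])
  })
  allv <- unlist(sets)
  if (length(unique(allv)) == 1L) {
    return(list(statistic = NA_real_, p_raw = 1,
                method = "degenerate", degenerate = TRUE))
  }
  if (group$test_kind == "two_sample") {
    mann_whitney(sets[[1]], sets[[2]], exact_max = exact_max)
  } else {
    kruskal_wallis(sets)
  }
}

mann_whitney <- function(x, y, exact_max = 20) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_max) {
    combs <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    return(list(statistic = u, p_raw = p, method = "mann-whitney exact",
                degenerate = FALSE))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u, p_raw = p, method = "mann-whitney normal approx",
       degenerate = FALSE)
}

kruskal_wallis <- function(sets) {
  allv <- unlist(sets)
  n <- length(allv)
  r <- rank(allv)
  idx <- rep(seq_along(sets), lengths(sets))
  rbar <- tapply(r, idx, sum)
  ni <- lengths(sets)
  h <- 12 / (n * (n + 1)) * sum(rbar^2 / ni) - 3 * (n + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h <- h / corr
  df <- length(sets) - 1
  p <- stats::pchisq(h, df, lower.tail = FALSE)
  list(statistic = h, p_raw = p, method = "kruskal-wallis", degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed,
#'   propagated).
#' @return Adjusted p-values in the original order, monotone over the
#'   sorted sequence and clipped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(pv[o] * m / (m:1)))
  out[ok[o]] <- adj
  out
}

#' Per-feature differential testing with FDR control
#'
#' Applies [rank_test()] to every row of a features x samples matrix for
#' one comparison group and adjusts the raw p-values with
#' [bh_adjust()]. Zero-variance features (e.g. reactions whose flux is
#' always zero) are excluded from testing and reported separately, to
#' avoid degenerate rank statistics.
#'
#' @param values An `omic_matrix` or features x samples matrix.
#' @param group A `comparison_group`.
#' @param exact_max Passed to [rank_test()].
#' @return A `differential_result`: data.frame with columns
#'   `feature_id`, `statistic`, `p_raw`, `p_adj`; attributes `group`
#'   (name), `layer`, `excluded` (zero-variance feature ids).
#' @export
diff_test <- function(values, group, exact_max = 20) {
  samples <- unlist(group$member_sets)
  miss <- setdiff(samples, colnames(values))
  if (length(miss)) {
    stop("samples absent from matrix: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  v <- unclass(values)[, samples, drop = FALSE]
  keep <- apply(v, 1, function(x) length(unique(x)) > 1)
  excluded <- rownames(v)[!keep]
  v <- v[keep, , drop = FALSE]
  res <- lapply(rownames(v), function(f) {
    rank_test(group, stats::setNames(v[f, ], colnames(v)),
              exact_max = exact_max)
  })
  df <- data.frame(
    feature_id = rownames(v),
    statistic = vapply(res, function(x) x$statistic, numeric(1)),
    p_raw = vapply(res, function(x) x$p_raw, numeric(1)),
    stringsAsFactors = FALSE
  )
  df$p_adj <- bh_adjust(df$p_raw)
  attr(df, "group") <- group$name
  attr(df, "layer") <- if (inherits(values, "omic_matrix"))
    omic_layer(values) else "unknown"
  attr(df, "excluded") <- excluded
  class(df) <- c("differential_result", "data.frame")
  df
}

# run an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
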