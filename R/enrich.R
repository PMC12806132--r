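#' Hypergeometric point probability
#'
#' `P(X = x) = C(m, x) C(N - m, n - x) / C(N, n)`: the probability of
#' drawing exactly `x` pathway members when `n` features are sampled
#' without replacement from a universe of `N` features of which `m`
#' belong to the pathway. Computed in log space so large universes do
#' not overflow the binomial coefficients.
#'
#' @param N Universe size.
#' @param m Pathway (term) size.
#' @param n Number of drawn (significant) features.
#' @param x Observed overlap.
#' @return The point probability (0 outside the support).
#' @export
hypergeom_pmf <- function(N, m, n, x) {
  vals <- c(N, m, n, x)
  if (any(vals != floor(vals)) || any(c(N, m, n) < 0) ||
      m > N || n > N) {
    stop("invalid hypergeometric parameters", call. = FALSE)
  }
  if (x < 0 || x > min(m, n) || (n - x) > (N - m)) return(0)
  exp(lchoose(m, x) + lchoose(N - m, n - x) - lchoose(N, n))
}

#' Upper-tail hypergeometric probability P(X >= x)
#'
#' Sum of [hypergeom_pmf()] over `k = x .. min(m, n)`; includes the
#' observed value, so `x = 0` gives 1.
#'
#' @inheritParams hypergeom_pmf
#' @return The tail probability.
#' @export
hypergeom_tail <- function(N, m, n, x) {
  if (x <= 0) return(1)
  hi <- min(m, n)
  if (x > hi) return(0)
  sum(vapply(x:hi, function(k) hypergeom_pmf(N, m, n, k), numeric(1)))
}

#' Build a feature -> term map
#'
#' @param terms Named list: term label -> character vector of feature
#'   ids.
#' @param universe Character vector of all feature ids under
#'   consideration; every mapped feature must belong to it.
#' @return A `term_map` object.
#' @export
term_map <- function(terms, universe) {
  universe <- unique(as.character(universe))
  if (length(terms) == 0) stop("term map needs at least one term",
                               call. = FALSE)
  terms <- lapply(terms, function(f) unique(as.character(f)))
  stray <- setdiff(unlist(terms), universe)
  if (length(stray)) {
    stop("term features outside universe: ",
         paste(utils::head(stray, 3), collapse = ", "), call. = FALSE)
  }
  structure(list(terms = terms, universe = universe), class = "term_map")
}

#' Subsystem term map of a metabolic model
#'
#' Universe = all reactions carrying a subsystem label; terms = the
#' subsystems. When the model was made irreversible, forward/backward
#' copies are collapsed to their parent reaction id first so a pathway
#' is not double-counted.
#'
#' @param model A `metabolic_model`.
#' @param collapse_split Collapse `_f`/`_b` suffixes (default `TRUE`).
#' @return A `term_map` over reaction ids.
#' @export
subsystem_term_map <- function(model, collapse_split = TRUE) {
  idx <- subsystem_index(model)
  if (collapse_split) {
    idx <- lapply(idx, function(ids) unique(collapse_split_ids(ids)))
  }
  term_map(idx, unique(unlist(idx)))
}

#' Read a feature -> term map from TSV or GMT
#'
#' TSV: two columns `feature_id`, `term` (header optional, detected).
#' GMT: one term per line, tab-separated `term`, `description`,
#' features.
#'
#' @param path File path.
#' @param format `"tsv"`, `"gmt"` or `"auto"` (by extension).
#' @param universe Optional universe; defaults to the union of mapped
#'   features.
#' @return A `term_map`.
#' @export
read_term_map <- function(path, format = c("auto", "tsv", "gmt"),
                          universe = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    terms <- stats::setNames(
      lapply(parts, function(p) p[-(1:2)]),
      vapply(parts, `[`, "", 1))
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE,
                            col.names = c("feature_id", "term"))
    if (identical(tolower(df[1, 1]), "feature_id")) df <- df[-1, ]
    terms <- split(df$feature_id, df$term)
  }
  term_map(terms, universe %||% unique(unlist(terms)))
}

#' Hypergeometric over-representation of terms
#'
#' For each term, counts the overlap `x` between the significant set and
#' the term's features and computes the upper-tail probability
#' `P(X >= x)`; a term is called over-represented when that tail falls
#' below `alpha` (0.1 by convention here). No multiple-testing
#' correction is applied across terms — FDR control belongs to the
#' feature-level tests that produced the significant set.
#'
#' @param significant Character vector of significant feature ids (must
#'   lie in the map's universe).
#' @param tmap A `term_map`.
#' @param alpha Over-representation threshold on the tail probability.
#' @return data.frame with columns `term`, `N`, `m`, `n`, `x`,
#'   `p_point`, `p_tail`, `over_represented`, sorted by `p_tail`.
#' @export
enrich_terms <- function(significant, tmap, alpha = 0.1) {
  significant <- unique(as.character(significant))
  stray <- setdiff(significant, tmap$universe)
  if (length(stray)) {
    stop("significant features outside universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  N <- length(tmap$universe)
  n <- length(significant)
  rows <- lapply(names(tmap$terms), function(tm) {
    feats <- tmap$terms[[tm]]
    m <- length(feats)
    x <- length(intersect(significant, feats))
    data.frame(term = tm, N = N, m = m, n = n, x = x,
               p_point = hypergeom_pmf(N, m, n, x),
               p_tail = hypergeom_tail(N, m, n, x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$over_represented <- out$p_tail < alpha
  out[order(out$p_tail, out$term), , drop = FALSE]
}

#' Term x comparison matrix of enrichment tail probabilities
#'
#' Reshapes per-comparison [enrich_terms()] results into the wide
#' matrix used for heatmap display. Terms absent from a comparison's
#' result are `NA` (explicit missingness), never silently 1.
#'
#' @param results Named list of [enrich_terms()] data.frames, one per
#'   comparison.
#' @return List with `wide` (numeric matrix terms x comparisons of
#'   `p_tail`) and `long` (stacked data.frame with a `comparison`
#'   column).
#' @export
enrichment_heat_table <- function(results) {
  stopifnot(is.list(results), !is.null(names(results)))
  long <- do.call(rbind, lapply(names(results), function(cmp) {
    df <- results[[cmp]]
    data.frame(comparison = cmp, df, stringsAsFactors = FALSE)
  }))
  terms <- sort(unique(long$term))
  comps <- names(results)
  wide <- matrix(NA_real_, length(terms), length(comps),
                 dimnames = list(terms, comps))
  for (cmp in comps) {
    df <- results[[cmp]]
    wide[df$term, cmp] <- df$p_tail
  }
  list(wide = wide, long = long)
}
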