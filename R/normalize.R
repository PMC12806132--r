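#' Construct an omic feature matrix
#'
#' A thin wrapper around a numeric features x samples matrix carrying a
#' layer tag: `TX` (transcript), `GX` (copy number), `PX` (protein),
#' `JX` (flux) or `reaction_expression`. Row names are feature ids
#' (genes, reactions, proteins), column names are sample ids.
#'
#' @param values Numeric matrix with row and column names.
#' @param layer Layer tag string.
#' @return An `omic_matrix` (matrix subclass with a `layer` attribute).
#' @export
omic_matrix <- function(values, layer = "TX") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("omic matrix needs feature row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids in omic matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in omic matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("omic matrix values must be finite", call. = FALSE)
  }
  structure(values, layer = layer, class = c("omic_matrix", "matrix", "array"))
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat(sprintf("<omic_matrix layer=%s: %d features x %d samples>\n",
              attr(x, "layer"), nrow(x), ncol(x)))
  invisible(x)
}

#' Layer tag of an omic matrix
#' @param x An `omic_matrix`.
#' @return The layer string.
#' @export
omic_layer <- function(x) attr(x, "layer")

#' Read an omic matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#'
#' @param path File path.
#' @param layer Layer tag to attach.
#' @param sep Field separator (`"\t"` default; `","` for CSV).
#' @return An `omic_matrix`.
#' @export
read_omic_matrix <- function(path, layer = "TX", sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  omic_matrix(as.matrix(df), layer = layer)
}

#' Write an omic matrix as TSV
#'
#' @param x An `omic_matrix` (or plain named matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omic_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference-gene-anchored min-max normalization
#'
#' Rescales each sample so that the per-sample minimum maps to 0 and the
#' expression of a highly, stably expressed reference gene (pyruvate
#' kinase, `PKM`, by convention for human expression data) maps to 1:
#' `e'(g,s) = (e(g,s) - min_g e(g,s)) / (e(ref,s) - min_g e(g,s))`.
#' Genes exceeding the reference are clipped to 1, so the output lies in
#' `[0, 1]` — the range expected by the expression-capped flux bounds.
#' Anchoring to one constitutive gene (rather than the per-sample
#' maximum) makes samples comparable across batches.
#'
#' @param expr An `omic_matrix` of nonnegative expression values.
#' @param reference_gene Row name of the reference gene (default
#'   `"PKM"`).
#' @return A normalized `omic_matrix` (same layer tag).
#' @examples
#' m <- omic_matrix(matrix(c(10, 50, 100), 3, 1,
#'                         dimnames = list(c("a", "b", "PKM"), "s1")))
#' normalize_reference_minmax(m)
#' @export
normalize_reference_minmax <- function(expr, reference_gene = "PKM") {
  if (!reference_gene %in% rownames(expr)) {
    stop("reference gene '", reference_gene, "' not present in matrix",
         call. = FALSE)
  }
  v <- unclass(expr)
  mins <- apply(v, 2, min)
  refs <- v[reference_gene, ]
  bad <- refs <= mins
  if (any(bad)) {
    stop("degenerate sample(s): reference gene does not exceed the ",
         "sample minimum: ", paste(colnames(v)[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- sweep(sweep(v, 2, mins, "-"), 2, refs - mins, "/")
  out[out > 1] <- 1
  omic_matrix(out, layer = omic_layer(expr))
}

#' Elementwise log2 transform with pseudocount
#'
#' Optional pre-step for heavy-tailed FPKM-like values.
#'
#' @param expr An `omic_matrix` with nonnegative values.
#' @param pseudocount Nonnegative offset added before `log2`.
#' @return Transformed `omic_matrix`.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    stop("pseudocount must be a single nonnegative number", call. = FALSE)
  }
  if (any(unclass(expr) < 0)) {
    stop("log_transform requires nonnegative values", call. = FALSE)
  }
  omic_matrix(log2(unclass(expr) + pseudocount), layer = omic_layer(expr))
}
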