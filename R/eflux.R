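#' Specify the growth medium for flux simulations
#'
#' Tissue-derived samples are simulated semi-quantitatively: a set of
#' exchange reactions (glucose, oxygen, amino acids, growth factors) is
#' allowed to carry uptake flux up to a common limit, all other uptake
#' routes are closed.
#'
#' @param allowed_uptake Character vector of exchange reaction ids
#'   (original, pre-split ids are accepted).
#' @param uptake_limit Positive flux cap per allowed exchange.
#' @return A `medium_spec` object.
#' @export
medium_spec <- function(allowed_uptake, uptake_limit = 10) {
  if (!is.numeric(uptake_limit) || uptake_limit <= 0) {
    stop("uptake_limit must be > 0", call. = FALSE)
  }
  structure(list(allowed_uptake = unique(as.character(allowed_uptake)),
                 uptake_limit = uptake_limit),
            class = "medium_spec")
}

model_is_irreversible <- function(model) {
  all(vapply(model$reactions, function(r) r$lower_bound >= 0, logical(1)))
}

#' Cap reaction bounds from one sample's expression (E-flux)
#'
#' For every reaction whose GPR rule yields a minSum activity score `a`
#' (see [evaluate_gpr_minsum()]), the upper bound is set to `a * vmax`
#' with `a` capped at 1 (isozyme sums can exceed 1) and the lower bound
#' to 0. Reactions without a GPR, or whose genes are all absent from the
#' data, keep their default bounds. Exchange uptake routes are then
#' closed except for those named in `medium`, which are opened to the
#' medium's uptake limit.
#'
#' @param model An irreversible `metabolic_model` (see
#'   [make_irreversible()]).
#' @param expr Normalized `omic_matrix` (values in `[0, 1]`) or a named
#'   numeric vector of per-gene scores.
#' @param sample Sample id (column of `expr`); ignored when `expr` is a
#'   vector.
#' @param vmax Flux-scale constant mapping a score of 1 to an upper
#'   bound (default 1000, the conventional "unbounded" magnitude).
#' @param medium Optional `medium_spec`.
#' @param missing_policy Passed to [evaluate_gpr_minsum()].
#' @return List with `model` (the constrained copy) and `n_constrained`
#'   (number of reactions whose bounds were expression-capped).
#' @export
assign_eflux_bounds <- function(model, expr, sample = NULL, vmax = 1000,
                                medium = NULL,
                                missing_policy = c("skip", "zero")) {
  missing_policy <- match.arg(missing_policy)
  if (!model_is_irreversible(model)) {
    stop("assign_eflux_bounds requires an irreversible model; ",
         "call make_irreversible() first", call. = FALSE)
  }
  if (inherits(expr, "omic_matrix") || is.matrix(expr)) {
    if (is.null(sample) || !sample %in% colnames(expr)) {
      stop("sample '", sample, "' not found in expression matrix",
           call. = FALSE)
    }
    ev <- stats::setNames(unclass(expr)[, sample], rownames(expr))
  } else {
    ev <- expr
  }
  n_constrained <- 0L
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    if (is.null(r$gpr)) next
    a <- evaluate_gpr_minsum(r$gpr, ev, missing_policy)
    if (is.na(a)) next
    a <- min(max(a, 0), 1)
    model$reactions[[i]]$lower_bound <- 0
    model$reactions[[i]]$upper_bound <- a * vmax
    n_constrained <- n_constrained + 1L
  }
  if (!is.null(medium)) {
    ex_ids <- exchange_reactions(model)
    allowed <- unique(c(medium$allowed_uptake,
                        paste0(medium$allowed_uptake, "_b"),
                        paste0(medium$allowed_uptake, "_f")))
    for (id in ex_ids) {
      r <- model$reactions[[id]]
      # uptake direction produces its single metabolite from nothing
      if (unname(r$stoichiometry[1]) > 0) {
        ub <- if (id %in% allowed) medium$uptake_limit else 0
        model$reactions[[id]]$upper_bound <- ub
        model$reactions[[id]]$lower_bound <- 0
      }
    }
  }
  list(model = model, n_constrained = n_constrained)
}

#' Flux balance analysis
#'
#' Maximises the objective reaction's flux subject to steady-state mass
#' balance `S v = 0` and the model's flux bounds, via the package's
#' deterministic bounded-variable simplex ([lp_solve()]).
#'
#' @param model A `metabolic_model`.
#' @param objective_id Optional override of the model's objective
#'   reaction (e.g. a maintenance or secretion objective).
#' @return List with `fluxes` (named vector, `NULL` unless optimal),
#'   `objective` and `status` (`"optimal"`/`"infeasible"`/
#'   `"unbounded"`).
#' @export
solve_fba <- function(model, objective_id = NULL) {
  obj <- objective_id %||% model$objective_id
  ids <- reaction_ids(model)
  if (!obj %in% ids) stop("unknown objective reaction: ", obj, call. = FALSE)
  S <- stoich_matrix(model)
  lb <- vapply(model$reactions, function(r) r$lower_bound, numeric(1))
  ub <- vapply(model$reactions, function(r) r$upper_bound, numeric(1))
  cc <- as.numeric(ids == obj)
  res <- lp_solve(cc, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
  if (res$status != "optimal") {
    return(list(fluxes = NULL, objective = NA_real_, status = res$status))
  }
  list(fluxes = stats::setNames(res$x, ids),
       objective = res$objective, status = "optimal")
}

#' Per-sample growth-maximising fluxes for a cohort
#'
#' Runs [assign_eflux_bounds()] + [solve_fba()] for every sample column
#' of a normalized expression matrix, producing the fluxome (`JX`) layer:
#' a reactions x samples matrix of optimal fluxes. Infeasible samples
#' are recorded (zero-filled column, status flag) and the pipeline
#' continues.
#'
#' @inheritParams assign_eflux_bounds
#' @param expr Normalized `omic_matrix` (genes x samples).
#' @param objective_id Optional objective override passed to
#'   [solve_fba()].
#' @return An `omic_matrix` with layer `"JX"` and attributes
#'   `objective_values` (named per-sample numeric), `solver_status`
#'   (named character) and `n_constrained`.
#' @export
fluxome_for_cohort <- function(model, expr, vmax = 1000, medium = NULL,
                               missing_policy = "skip",
                               objective_id = NULL) {
  samples <- colnames(expr)
  ids <- reaction_ids(model)
  vals <- matrix(0, nrow = length(ids), ncol = length(samples),
                 dimnames = list(ids, samples))
  objv <- stats::setNames(rep(NA_real_, length(samples)), samples)
  status <- stats::setNames(character(length(samples)), samples)
  ncons <- NA_integer_
  for (s in samples) {
    con <- assign_eflux_bounds(model, expr, s, vmax = vmax, medium = medium,
                               missing_policy = missing_policy)
    ncons <- con$n_constrained
    sol <- solve_fba(con$model, objective_id = objective_id)
    status[s] <- sol$status
    if (sol$status == "optimal") {
      vals[, s] <- sol$fluxes[ids]
      objv[s] <- sol$objective
    }
  }
  n_bad <- sum(status != "optimal")
  if (n_bad > 0) {
    warning(n_bad, " sample(s) had no optimal flux solution: ",
            paste(samples[status != "optimal"], collapse = ", "),
            call. = FALSE)
  }
  out <- omic_matrix(vals, layer = "JX")
  attr(out, "objective_values") <- objv
  attr(out, "solver_status") <- status
  attr(out, "n_constrained") <- ncons
  out
}

#' Reaction-level expression scores for a cohort
#'
#' Applies the minSum GPR scoring to every reaction and sample, yielding
#' a reactions x samples matrix of "reaction gene expression values" —
#' the expression counterpart of the flux layer, used to check that flux
#' shifts track their transcriptional drivers. Reactions without a GPR
#' are omitted.
#'
#' @param model A `metabolic_model`.
#' @param expr Normalized `omic_matrix` (genes x samples).
#' @param missing_policy Passed to [evaluate_gpr_minsum()].
#' @return An `omic_matrix` with layer `"reaction_expression"`.
#' @export
reaction_expression <- function(model, expr, missing_policy = "skip") {
  keep <- Filter(function(r) !is.null(r$gpr), model$reactions)
  samples <- colnames(expr)
  vals <- matrix(NA_real_, nrow = length(keep), ncol = length(samples),
                 dimnames = list(vapply(keep, function(r) r$id, ""), samples))
  ev <- unclass(expr)
  for (s in samples) {
    col <- stats::setNames(ev[, s], rownames(expr))
    vals[, s] <- vapply(keep, function(r)
      evaluate_gpr_minsum(r$gpr, col, missing_policy), numeric(1))
  }
  drop_rows <- apply(vals, 1, function(x) all(is.na(x)))
  vals <- vals[!drop_rows, , drop = FALSE]
  vals[is.na(vals)] <- 0
  omic_matrix(vals, layer = "reaction_expression")
}
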