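#' Solve a bounded-variable linear program by the primal simplex method
#'
#' Solves `max/min c'x  subject to  A x = b,  lb <= x <= ub` with a dense
#' two-phase bounded-variable simplex. Bland's smallest-index rule is used
#' for both entering and leaving choices, which guarantees termination
#' under degeneracy and makes the returned vertex deterministic — the
#' property the per-sample flux pipeline relies on for reproducibility.
#'
#' Problem sizes in this package (toy networks, tens of variables) are far
#' below the scale where a sparse/revised implementation would matter.
#'
#' @param c_obj Objective coefficients (length n).
#' @param A Constraint matrix (m x n).
#' @param b Right-hand side (length m).
#' @param lb,ub Variable bounds (length n, finite lower bounds; `Inf`
#'   upper bounds allowed).
#' @param maximize Logical; maximise (default) or minimise.
#' @param tol Feasibility/optimality tolerance.
#' @param max_iter Iteration cap (error if exceeded).
#' @return List with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (solution, `NULL` unless optimal) and
#'   `objective`.
#' @export
lp_solve <- function(c_obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(c_obj) == n, length(b) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("lower bounds must be finite", call. = FALSE)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  cc <- if (maximize) as.numeric(c_obj) else -as.numeric(c_obj)

  # shift to z = x - lb in [0, span]
  span <- ub - lb
  b2 <- as.numeric(b - A %*% lb)
  flip <- b2 < 0
  A2 <- A; A2[flip, ] <- -A2[flip, , drop = FALSE]
  b2[flip] <- -b2[flip]

  # columns: n structural + m artificial
  Afull <- cbind(A2, diag(m))
  span_full <- c(span, rep(Inf, m))
  ntot <- n + m
  basis <- (n + 1L):ntot
  at_upper <- rep(FALSE, ntot)          # for nonbasic variables
  xB <- b2

  run_phase <- function(costs, allow_enter, basis, at_upper, xB) {
    for (it in seq_len(max_iter)) {
      B <- Afull[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) stop("singular basis in simplex", call. = FALSE)
      y <- drop(crossprod(Binv, costs[basis]))
      nonbasic <- setdiff(seq_len(ntot), basis)
      nonbasic <- nonbasic[allow_enter[nonbasic]]
      if (length(nonbasic) == 0L) {
        return(list(status = "optimal", basis = basis,
                    at_upper = at_upper, xB = xB))
      }
      d <- costs[nonbasic] - drop(y %*% Afull[, nonbasic, drop = FALSE])
      elig <- (!at_upper[nonbasic] & d > tol) |
              (at_upper[nonbasic] & d < -tol)
      if (!any(elig)) {
        return(list(status = "optimal", basis = basis,
                    at_upper = at_upper, xB = xB))
      }
      j <- min(nonbasic[elig])                 # Bland: smallest index
      sigma <- if (at_upper[j]) -1 else 1      # direction of change of z_j
      w <- drop(Binv %*% Afull[, j])
      # ratio test: z_j moves by t >= 0 in direction sigma;
      # basic values change by -sigma * t * w
      t_best <- span_full[j]                   # bound flip
      leave <- 0L                              # 0 = flip
      leave_to_upper <- FALSE
      for (i in seq_len(m)) {
        di <- sigma * w[i]
        if (di > tol) {
          ti <- xB[i] / di
          if (ti < t_best - tol ||
              (ti < t_best + tol && leave != 0L && basis[i] < basis[leave])) {
            t_best <- ti; leave <- i; leave_to_upper <- FALSE
          }
        } else if (di < -tol && is.finite(span_full[basis[i]])) {
          ti <- (span_full[basis[i]] - xB[i]) / (-di)
          if (ti < t_best - tol ||
              (ti < t_best + tol && leave != 0L && basis[i] < basis[leave])) {
            t_best <- ti; leave <- i; leave_to_upper <- TRUE
          }
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded", basis = basis,
                    at_upper = at_upper, xB = xB))
      }
      t_best <- max(t_best, 0)
      xB <- xB - sigma * t_best * w
      if (leave == 0L) {
        at_upper[j] <- !at_upper[j]            # bound flip, basis unchanged
      } else {
        lv <- basis[leave]
        at_upper[lv] <- leave_to_upper
        basis[leave] <- j
        xB[leave] <- if (at_upper[j]) span_full[j] - t_best else t_best
        at_upper[j] <- FALSE                   # now basic
      }
    }
    stop("simplex iteration limit reached", call. = FALSE)
  }

  # Phase 1: drive artificials to zero
  costs1 <- c(rep(0, n), rep(-1, m))
  allow1 <- rep(TRUE, ntot)
  ph1 <- run_phase(costs1, allow1, basis, at_upper, xB)
  if (ph1$status != "optimal") {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  art_val <- sum(ph1$xB[ph1$basis > n])
  if (art_val > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }

  # Phase 2: artificials frozen (span 0 so basic ones cannot move off
  # zero, and they may never re-enter)
  span_full[(n + 1L):ntot] <- 0
  costs2 <- c(cc, rep(0, m))
  allow2 <- c(rep(TRUE, n), rep(FALSE, m))
  ph2 <- run_phase(costs2, allow2, ph1$basis, ph1$at_upper, ph1$xB)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  z <- numeric(ntot)
  z[seq_len(ntot)][ph2$at_upper & is.finite(span_full)] <-
    span_full[ph2$at_upper & is.finite(span_full)]
  z[ph2$basis] <- ph2$xB
  x <- z[seq_len(n)] + lb
  # clamp tiny numerical spill
  x <- pmin(pmax(x, lb), ub)
  obj <- sum(as.numeric(c_obj) * x)
  list(status = "optimal", x = x, objective = obj)
}
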