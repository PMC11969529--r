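# Internal LP/QP layer on quadprog.
#
# LPs (FBA, FVA, task checks) are solved exactly through the strictly
# convex program  min eps*||v||^2 - c'v  s.t.  Sv = 0, l <= v <= u.
# For eps below a problem-dependent threshold this returns the least-norm
# optimal LP solution exactly (exact regularization); we certify eps by
# agreement of the linear objective across two eps values. QPs (MOMA,
# second-stage flux minimization) are native quadprog problems.
#
# quadprog's Goldfarb-Idnani method requires linearly independent equality
# constraints; stoichiometric matrices routinely contain dependent rows
# (conserved moieties), so equality rows are QR-reduced first and the
# dropped rows verified on the returned solution.

.INF_BOUND <- 1e30

# Reduce equality system E x = b to independent rows; returns row indices.
.eq_independent_rows <- function(E, tol = 1e-10) {
  if (nrow(E) == 0L) return(integer(0))
  qr_t <- qr(t(E), tol = tol)
  sort(qr_t$pivot[seq_len(qr_t$rank)])
}

# Core constrained quadratic solve:
#   min  (1/2) x' (2*q) x  -  d' x   s.t.  E x = b (reduced), l <= x <= u
# with q a scalar diagonal weight. Returns list(status, x).
.cqp <- function(q, d, E, b, lb, ub) {
  n <- length(d)
  fixed <- is.finite(lb) & is.finite(ub) & (ub - lb) < 1e-12
  if (any(fixed)) {
    Efix <- matrix(0, sum(fixed), n)
    Efix[cbind(seq_len(sum(fixed)), which(fixed))] <- 1
    E <- rbind(E, Efix)
    b <- c(b, (lb[fixed] + ub[fixed]) / 2)
  }
  keep <- .eq_independent_rows(E)
  Er <- E[keep, , drop = FALSE]
  br <- b[keep]
  has_lb <- !fixed & lb > -.INF_BOUND
  has_ub <- !fixed & ub < .INF_BOUND
  Ain <- rbind(diag(n)[has_lb, , drop = FALSE],
               -diag(n)[has_ub, , drop = FALSE])
  bin <- c(lb[has_lb], -ub[has_ub])
  Amat <- t(rbind(Er, Ain))
  bvec <- c(br, bin)
  Dmat <- diag(2 * q, n)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, d, Amat, bvec, meq = nrow(Er)),
    error = function(e) e
  )
  if (inherits(sol, "error")) {
    status <- if (grepl("inconsistent", conditionMessage(sol))) "infeasible" else "error"
    return(list(status = status, x = NULL, message = conditionMessage(sol)))
  }
  x <- sol$solution
  # verify constraints dropped in the QR reduction (and overall residuals)
  if (nrow(E) > 0) {
    resid <- max(abs(E %*% x - b))
    if (resid > 1e-6) return(list(status = "infeasible", x = NULL,
                                  message = sprintf("equality residual %.3g", resid)))
  }
  list(status = "optimal", x = x)
}

# Exact LP: optimize c'x s.t. E x = b, l <= x <= u, via the bounded
# simplex. sense "max" or "min". Returns list(status, x, objective).
.lp_solve <- function(cc, E, b, lb, ub, sense = "max") {
  .simplex_lp(cc, E, b, lb, ub, maximize = identical(sense, "max"))
}

# Nearest-point QP: min ||x - ref||^2 s.t. E x = b, l <= x <= u.
# quadprog's active-set method is exact and fast when it works, but its
# Goldfarb-Idnani pivoting breaks down on the heavily degenerate
# constraint sets of merged flux models; Dykstra's alternating-projection
# scheme (the problem IS a projection onto {Ex=b} intersected with the
# bound box) is then used as the robust fallback, including for the
# infeasibility verdict.
.qp_nearest <- function(ref, E, b, lb, ub) {
  r <- .cqp(1, 2 * ref, E, b, lb, ub)
  if (r$status == "optimal") {
    return(list(status = "optimal", x = r$x, distance2 = sum((r$x - ref)^2)))
  }
  .dykstra_project(ref, E, b, lb, ub)
}

# Exact projection of `ref` onto {x : E x = b, lb <= x <= ub} by Dykstra's
# algorithm (correction term on the box only; the affine set needs none).
.dykstra_project <- function(ref, E, b, lb, ub, tol = 1e-12,
                             max_iter = 300000L, check_every = 200L) {
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL,
                message = "inconsistent bounds"))
  }
  keep <- .eq_independent_rows(E)
  E <- E[keep, , drop = FALSE]
  b <- b[keep]
  if (nrow(E) == 0L) {
    x <- pmin(pmax(ref, lb), ub)
    return(list(status = "optimal", x = x, distance2 = sum((x - ref)^2)))
  }
  ch <- chol(tcrossprod(E) + 1e-12 * diag(nrow(E)))
  proj_aff <- function(x) {
    x - as.numeric(crossprod(E, backsolve(ch, forwardsolve(t(ch), E %*% x - b))))
  }
  x <- ref
  pbox <- numeric(length(ref))
  prev_feas <- Inf
  for (it in seq_len(max_iter)) {
    y <- proj_aff(x)
    z <- y + pbox
    x2 <- pmin(pmax(z, lb), ub)
    pbox <- z - x2
    if (it %% check_every == 0L) {
      feas <- max(abs(E %*% x2 - b))
      step <- max(abs(x2 - x))
      if (step < tol && feas < 1e-9) {
        return(list(status = "optimal", x = x2, distance2 = sum((x2 - ref)^2)))
      }
      if (step < tol && feas > 1e-7 && abs(feas - prev_feas) < 1e-12) {
        # the two sets do not intersect
        return(list(status = "infeasible", x = NULL,
                    message = sprintf("alternating projections stalled at residual %.3g", feas)))
      }
      prev_feas <- feas
    }
    x <- x2
  }
  list(status = "error", x = NULL, message = "projection did not converge")
}

# Assemble dense equality system (S v = 0 plus optional extra rows) and
# bound vectors for a model.
.model_lp_parts <- function(model) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  bnd <- reaction_bounds(model)
  list(S = S, lb = bnd$lower_bound, ub = bnd$upper_bound, ids = bnd$id)
}

.flux_state <- function(model, x, objective, status, distance = NA_real_) {
  ids <- reaction_ids(model)
  fluxes <- if (is.null(x)) stats::setNames(rep(NA_real_, length(ids)), ids)
            else stats::setNames(x, ids)
  resid <- NA_real_
  if (!is.null(x)) {
    S <- build_stoichiometric_matrix(model)
    resid <- if (nrow(S)) max(abs(as.numeric(S %*% x))) else 0
  }
  structure(list(fluxes = fluxes, objective_value = objective, status = status,
                 steady_state_residual = resid, distance = distance),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("flux_state: status %s, objective %s, ||S v||_inf = %s\n",
              x$status,
              if (is.na(x$objective_value)) "NA" else format(x$objective_value, digits = 6),
              if (is.na(x$steady_state_residual)) "NA"
              else format(x$steady_state_residual, digits = 3)))
  invisible(x)
}

# Resolve an objective spec (reaction id(s) or named coefficients) into a
# dense coefficient vector over model reactions.
.objective_vector <- function(model, objective) {
  ids <- reaction_ids(model)
  cc <- stats::setNames(rep(0, length(ids)), ids)
  if (is.character(objective)) {
    missing <- setdiff(objective, ids)
    if (length(missing)) {
      stop(sprintf("objective reaction(s) not in model: %s",
                   paste(missing, collapse = ", ")))
    }
    cc[objective] <- 1
  } else if (is.numeric(objective) && !is.null(names(objective))) {
    missing <- setdiff(names(objective), ids)
    if (length(missing)) {
      stop(sprintf("objective reaction(s) not in model: %s",
                   paste(missing, collapse = ", ")))
    }
    cc[names(objective)] <- objective
  } else {
    stop("objective must be reaction id(s) or a named coefficient vector")
  }
  unname(cc)
}
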