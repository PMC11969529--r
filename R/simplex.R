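# Dense two-phase bounded-variable primal simplex.
#
# Solves   max c'x   s.t.  A x = b,  l <= x <= u.  Infinite bounds are
# clamped to a large box and unboundedness detected from solutions on the
# box. Flux-balance LPs are heavily degenerate (many reactions pinned at
# zero), which defeats active-set QP approaches, so the LP core is a
# textbook simplex: Dantzig pricing with a Bland's-rule fallback for
# anti-cycling, and index-based tie-breaks so solutions are
# bit-reproducible.
#
# Returns list(status = "optimal"|"infeasible"|"unbounded"|"error",
#              x, objective).

.SIMPLEX_BOX <- 1e7

.simplex_lp <- function(cc, A, b, lb, ub, maximize = TRUE,
                        tol = 1e-9, max_iter = 100000L) {
  m <- nrow(A); n <- ncol(A)
  lb <- pmax(lb, -.SIMPLEX_BOX)
  ub <- pmin(ub, .SIMPLEX_BOX)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  if (!maximize) cc <- -cc
  if (m == 0L) {
    x <- ifelse(cc > 0, ub, lb)
    obj <- sum(cc * x)
    return(list(status = "optimal", x = x,
                objective = if (maximize) obj else -obj))
  }

  # start: structural variables nonbasic at the bound nearer zero,
  # signed artificials basic holding the residual
  xN <- ifelse(abs(lb) <= abs(ub), lb, ub)
  r <- b - as.numeric(A %*% xN)
  sgn <- ifelse(r >= 0, 1, -1)
  N <- n + m
  Text <- sgn * A                     # B^{-1} A with B = diag(sgn)
  Text <- cbind(Text, diag(m))        # artificial columns (B^{-1} B = I)
  lb_e <- c(lb, rep(0, m))
  ub_e <- c(ub, pmax(abs(r), 0))
  basis <- n + seq_len(m)
  xb <- abs(r)
  is_basic <- c(rep(FALSE, n), rep(TRUE, m))
  at_ub <- c(abs(lb) > abs(ub), rep(FALSE, m))
  xval <- c(xN, rep(0, m))

  env <- environment()

  run_phase <- function(cost) {
    bland_after <- 2000L
    for (iter in seq_len(max_iter)) {
      cB <- cost[env$basis]
      d <- cost - as.numeric(crossprod(env$Text, cB))
      free_range <- env$ub_e - env$lb_e > tol
      cand <- which(!env$is_basic & free_range &
                      ((!env$at_ub & d > tol) | (env$at_ub & d < -tol)))
      if (!length(cand)) return("optimal")
      j <- if (iter > bland_after) min(cand) else cand[which.max(abs(d[cand]))]
      increasing <- !env$at_ub[j]
      delta <- if (increasing) -env$Text[, j] else env$Text[, j]
      blb <- env$lb_e[env$basis]; bub <- env$ub_e[env$basis]
      ti <- rep(Inf, m)
      dec <- delta < -tol; inc <- delta > tol
      ti[dec] <- (env$xb[dec] - blb[dec]) / (-delta[dec])
      ti[inc] <- (bub[inc] - env$xb[inc]) / delta[inc]
      ti[ti < 0] <- 0
      t_flip <- env$ub_e[j] - env$lb_e[j]
      t_ratio <- suppressWarnings(min(ti))
      t_min <- min(t_flip, t_ratio)
      if (t_min >= .SIMPLEX_BOX * 0.99) return("unbounded")
      if (t_flip < t_ratio - tol) {
        # entering variable traverses its whole range: bound flip
        env$xval[j] <- if (increasing) env$ub_e[j] else env$lb_e[j]
        env$at_ub[j] <- increasing
        env$xb <- env$xb + t_flip * delta
        next
      }
      leavers <- which(ti <= t_min + tol)
      leave <- leavers[which.min(env$basis[leavers])]
      piv <- env$Text[leave, j]
      if (abs(piv) < 1e-10) return("singular")
      out <- env$basis[leave]
      leave_to_ub <- delta[leave] > 0
      env$xb <- env$xb + t_min * delta
      enter_val <- if (increasing) env$lb_e[j] + t_min else env$ub_e[j] - t_min
      Trow <- env$Text[leave, ] / piv
      env$Text <- env$Text - outer(env$Text[, j], Trow)
      env$Text[leave, ] <- Trow
      env$xb[leave] <- enter_val
      env$basis[leave] <- j
      env$is_basic[j] <- TRUE
      env$is_basic[out] <- FALSE
      env$at_ub[out] <- leave_to_ub
      env$xval[out] <- if (leave_to_ub) env$ub_e[out] else env$lb_e[out]
    }
    "iterations"
  }

  if (any(xb > tol)) {
    res1 <- run_phase(c(rep(0, n), rep(-1, m)))
    if (res1 != "optimal") {
      return(list(status = "error", x = NULL, objective = NA_real_))
    }
    art <- (n + 1):N
    art_total <- sum(xb[basis > n]) + sum(xval[art][!is_basic[art]])
    if (art_total > 1e-7) {
      return(list(status = "infeasible", x = NULL, objective = NA_real_))
    }
  }
  ub_e[(n + 1):N] <- 0
  xval[(n + 1):N] <- 0
  res2 <- run_phase(c(cc, rep(0, m)))
  if (res2 == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  if (res2 != "optimal") {
    return(list(status = "error", x = NULL, objective = NA_real_))
  }
  x <- numeric(N)
  x[!is_basic] <- xval[!is_basic]
  x[basis] <- xb
  xs <- x[seq_len(n)]
  if (any(abs(xs) >= .SIMPLEX_BOX * 0.99)) {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  obj <- sum(cc * xs)
  list(status = "optimal", x = xs,
       objective = if (maximize) obj else -obj)
}
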