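# Independent oracles the solver tests are checked against. These stay
# deliberately naive: enumeration and closed forms, no reuse of the
# package's solution path.

# Enumerate all basic solutions of {S v = 0, lb <= v <= ub} and return the
# best objective value: choose n - rank(S) variables to fix at a bound
# (all bound sign combinations), solve the square system for the rest,
# keep feasible points. Exact for small n.
oracle_lp_vertex <- function(cc, S, lb, ub, sense = "max") {
  n <- ncol(S)
  S <- as.matrix(S)
  qrT <- qr(t(S))
  r <- qrT$rank
  rows <- sort(qrT$pivot[seq_len(r)])
  Sr <- S[rows, , drop = FALSE]
  free_count <- n - r
  best <- NULL
  best_x <- NULL
  combs <- utils::combn(n, free_count)
  for (ci in seq_len(ncol(combs))) {
    fixed <- combs[, ci]
    basic <- setdiff(seq_len(n), fixed)
    B <- Sr[, basic, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    grid <- as.matrix(expand.grid(rep(list(c(1, 2)), length(fixed))))
    for (gi in seq_len(nrow(grid))) {
      xf <- ifelse(grid[gi, ] == 1, lb[fixed], ub[fixed])
      rhs <- -Sr[, fixed, drop = FALSE] %*% xf
      xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xb)) next
      x <- numeric(n)
      x[fixed] <- xf
      x[basic] <- xb
      if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) next
      if (max(abs(S %*% x)) > 1e-8) next
      obj <- sum(cc * x)
      if (is.null(best) || (sense == "max" && obj > best) ||
          (sense == "min" && obj < best)) {
        best <- obj
        best_x <- x
      }
    }
  }
  list(objective = best, x = best_x)
}

# Closed-form equality-constrained projection of `ref` onto {S v = 0}
# with a set of variables clamped to fixed values: KKT linear system.
oracle_projection <- function(ref, S, fixed_idx = integer(0), fixed_val = numeric(0)) {
  n <- length(ref)
  S <- as.matrix(S)
  Efix <- matrix(0, length(fixed_idx), n)
  if (length(fixed_idx)) Efix[cbind(seq_along(fixed_idx), fixed_idx)] <- 1
  E <- rbind(S, Efix)
  b <- c(rep(0, nrow(S)), fixed_val)
  # min ||x - ref||^2 s.t. E x = b  =>  x = ref - E' (E E')^+ (E ref - b)
  x <- ref - as.numeric(t(E) %*% MASS::ginv(E %*% t(E)) %*% (E %*% ref - b))
  x
}

# Exact upper-tail hypergeometric probability by explicit combinatorial
# sums over overlap outcomes (no phyper).
oracle_hyper_upper <- function(x, K, N, n) {
  if (x <= 0) return(1)
  total <- choose(N, n)
  sum(vapply(x:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, numeric(1))) / total
}

# A small random flux network with a designated objective; guaranteed
# feasible (zero flux allowed) and bounded.
random_toy_lp <- function(n_rxn = 8, n_met = 5, seed = 1) {
  set.seed(seed)
  repeat {
    S <- matrix(0, n_met, n_rxn)
    for (j in seq_len(n_rxn)) {
      k <- sample(1:3, 1)
      idx <- sample(n_met, k)
      S[idx, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    }
    lb <- ifelse(stats::runif(n_rxn) < 0.5, 0, -stats::runif(n_rxn, 0, 5))
    ub <- stats::runif(n_rxn, 0, 10)
    cc <- numeric(n_rxn)
    cc[sample(n_rxn, 1)] <- 1
    if (qr(S)$rank < n_met) return(list(S = S, lb = lb, ub = ub, cc = cc))
  }
}
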