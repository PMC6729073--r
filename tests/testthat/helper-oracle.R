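# Independent brute-force LP oracle used to cross-check the production
# simplex solver: enumerates every basic point (each subset of nv active
# constraints), keeps the feasible ones and takes the best objective.
# Deliberately shares no code with the package's solver.

oracle_lp <- function(obj, A, dir, rhs, maximize = FALSE, tol = 1e-7) {
  A <- as.matrix(A)
  nv <- ncol(A)
  G <- rbind(A[dir == "<=", , drop = FALSE],
             -A[dir == ">=", , drop = FALSE],
             A[dir == "==", , drop = FALSE],
             -A[dir == "==", , drop = FALSE],
             -diag(nv))
  h <- c(rhs[dir == "<="], -rhs[dir == ">="],
         rhs[dir == "=="], -rhs[dir == "=="], rep(0, nv))
  best <- NA_real_
  for (k in seq_len(ncol(cmb <- utils::combn(nrow(G), nv)))) {
    S <- cmb[, k]
    x <- tryCatch(solve(G[S, , drop = FALSE], h[S]),
                  error = function(e) NULL)
    if (is.null(x) || !all(G %*% x <= h + tol)) next
    v <- sum(obj * x)
    if (is.na(best) || (maximize && v > best) || (!maximize && v < best)) {
      best <- v
    }
  }
  best
}

# Input-oriented radial score of DMU o by the oracle. Variables (theta, lambda).
oracle_radial <- function(X, Y, o, rts = "crs") {
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  A <- rbind(cbind(-X[o, ], t(X)), cbind(0, t(Y)))
  dir <- c(rep("<=", m), rep(">=", s))
  rhs <- c(rep(0, m), Y[o, ])
  if (rts == "vrs") {
    A <- rbind(A, c(0, rep(1, n))); dir <- c(dir, "=="); rhs <- c(rhs, 1)
  }
  oracle_lp(c(1, rep(0, n)), A, dir, rhs, maximize = FALSE)
}

# Input-oriented SBM score of DMU o by the oracle. Slacks are eliminated
# (s- = x_o - X'lambda), so the variables are lambda alone and
# rho = min_lambda (1/m) * sum_i (X'lambda)_i / x_io over the feasible set.
oracle_sbm <- function(X, Y, o, rts = "crs") {
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  A <- rbind(t(X), t(Y))
  dir <- c(rep("<=", m), rep(">=", s))
  rhs <- c(X[o, ], Y[o, ])
  if (rts == "vrs") {
    A <- rbind(A, rep(1, n)); dir <- c(dir, "=="); rhs <- c(rhs, 1)
  }
  obj <- as.numeric(X %*% (1 / X[o, ])) / m
  oracle_lp(obj, A, dir, rhs, maximize = FALSE)
}

# Small random positive dataset for property tests.
random_dmu_instance <- function(n = NULL, m = NULL, s = NULL) {
  if (is.null(n)) n <- sample(3:6, 1)
  if (is.null(m)) m <- sample(1:3, 1)
  if (is.null(s)) s <- sample(1:(4 - m), 1)
  X <- matrix(stats::runif(n * m, 0.5, 10), n, m)
  Y <- matrix(stats::runif(n * s, 0.5, 10), n, s)
  dmu_data(X, Y)
}
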