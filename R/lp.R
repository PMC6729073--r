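#' Solve a small dense linear program
#'
#' Minimises (or maximises) `obj %*% x` over `x >= 0` subject to general
#' linear constraints, with a two-phase primal simplex using Bland's
#' anti-cycling rule. The DEA envelopment programs solved in this package are
#' small (tens of variables and constraints), dense and frequently degenerate,
#' which is exactly the regime this implementation targets: Bland's rule
#' guarantees termination under degeneracy at the cost of speed that would
#' matter only for much larger programs.
#'
#' @param obj numeric objective coefficients, length `nv`.
#' @param mat constraint matrix, `nc x nv`.
#' @param dir character vector of constraint directions, each one of
#'   `"<="`, `">="`, `"=="`.
#' @param rhs numeric right-hand sides, length `nc`.
#' @param maximize logical; maximise instead of minimise.
#' @param tol pivot tolerance: entries with absolute value below `tol` are
#'   treated as zero.
#' @param feas_tol feasibility tolerance on the phase-1 objective.
#'
#' @return a list with elements `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `objval`, and `x` (the primal solution, length `nv`).
#' @keywords internal
solve_lp <- function(obj, mat, dir, rhs, maximize = FALSE,
                     tol = 1e-9, feas_tol = 1e-7) {
  mat <- as.matrix(mat)
  nc <- nrow(mat)
  nv <- ncol(mat)
  stopifnot(length(obj) == nv, length(dir) == nc, length(rhs) == nc)
  if (!all(dir %in% c("<=", ">=", "=="))) {
    stop("constraint directions must be one of '<=', '>=', '=='")
  }
  cost <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # Normalise to b >= 0, then add slack/surplus and artificial columns.
  flip <- rhs < 0
  mat[flip, , drop = FALSE] -> neg
  mat[flip, ] <- -neg
  rhs[flip] <- -rhs[flip]
  dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]

  n_slack <- sum(dir != "==")
  slack_cols <- matrix(0, nc, n_slack)
  slack_idx <- integer(nc)   # column (within slack block) of row's slack, 0 if none
  k <- 0L
  for (i in seq_len(nc)) {
    if (dir[i] != "==") {
      k <- k + 1L
      slack_cols[i, k] <- if (dir[i] == "<=") 1 else -1
      slack_idx[i] <- k
    }
  }
  # Artificials: one per row whose slack cannot start basic (>= or ==).
  art_rows <- which(dir != "<=")
  n_art <- length(art_rows)
  art_cols <- matrix(0, nc, n_art)
  if (n_art) art_cols[cbind(art_rows, seq_len(n_art))] <- 1

  Tmat <- cbind(mat, slack_cols, art_cols)
  ntot <- ncol(Tmat)
  art_set <- if (n_art) (nv + n_slack + 1L):ntot else integer(0)

  basis <- integer(nc)
  for (i in seq_len(nc)) {
    basis[i] <- if (dir[i] == "<=") nv + slack_idx[i] else 0L
  }
  if (n_art) basis[art_rows] <- art_set
  b <- rhs

  pivot <- function(Tmat, b, basis, cost_vec, allowed) {
    # Revised dense simplex on tableau (Tmat, b) for min cost_vec'x,
    # restricted to entering columns in `allowed`. Bland's rule.
    repeat {
      cb <- cost_vec[basis]
      # reduced costs: c_j - cb' B^-1 A_j ; maintain tableau in solved form,
      # so B^-1 A is Tmat itself and reduced cost is c_j - cb %*% Tmat[, j]
      red <- cost_vec - as.numeric(crossprod(cb, Tmat))
      ent <- 0L
      for (j in allowed) {
        if (red[j] < -tol && !(j %in% basis)) { ent <- j; break }
      }
      if (ent == 0L) return(list(Tmat = Tmat, b = b, basis = basis,
                                 status = "optimal"))
      col <- Tmat[, ent]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tmat = Tmat, b = b, basis = basis,
                                    status = "unbounded"))
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      leave <- cand[which.min(basis[cand])]   # Bland: smallest basis index
      piv <- Tmat[leave, ent]
      Tmat[leave, ] <- Tmat[leave, ] / piv
      b[leave] <- b[leave] / piv
      other <- setdiff(seq_len(nrow(Tmat)), leave)
      if (length(other)) {
        f <- Tmat[other, ent]
        Tmat[other, ] <- Tmat[other, , drop = FALSE] -
          outer(f, Tmat[leave, ])
        b[other] <- b[other] - f * b[leave]
      }
      basis[leave] <- ent
    }
  }

  all_cols <- seq_len(ntot)
  if (n_art) {
    cost1 <- c(rep(0, nv + n_slack), rep(1, n_art))
    res <- pivot(Tmat, b, basis, cost1, all_cols)
    Tmat <- res$Tmat; b <- res$b; basis <- res$basis
    phase1 <- sum(b[basis %in% art_set])
    if (phase1 > feas_tol) {
      return(list(status = "infeasible", objval = NA_real_, x = rep(NA_real_, nv)))
    }
    # Drive residual (degenerate) artificials out of the basis where possible.
    for (i in which(basis %in% art_set)) {
      row <- Tmat[i, seq_len(nv + n_slack)]
      j <- which(abs(row) > tol)
      if (length(j)) {
        ent <- j[1]
        piv <- Tmat[i, ent]
        Tmat[i, ] <- Tmat[i, ] / piv
        b[i] <- b[i] / piv
        other <- setdiff(seq_len(nc), i)
        f <- Tmat[other, ent]
        Tmat[other, ] <- Tmat[other, , drop = FALSE] - outer(f, Tmat[i, ])
        b[other] <- b[other] - f * b[i]
        basis[i] <- ent
      }
    }
  }

  keep <- setdiff(all_cols, art_set)
  cost2 <- c(cost, rep(0, n_slack))
  res <- pivot(Tmat, b, basis, c(cost2, rep(0, n_art)), keep)
  if (res$status == "unbounded") {
    return(list(status = "unbounded", objval = NA_real_, x = rep(NA_real_, nv)))
  }
  Tmat <- res$Tmat; b <- res$b; basis <- res$basis
  x <- numeric(ntot)
  x[basis] <- b
  objval <- sum(cost * x[seq_len(nv)])
  list(status = "optimal",
       objval = if (maximize) -objval else objval,
       x = x[seq_len(nv)])
}
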