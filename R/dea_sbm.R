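#' Transform undesirable outputs for DEA
#'
#' Outputs where lower is better (fall rate, unhandled-complaint rate,
#' major-accident incidence) cannot enter an envelopment program directly,
#' since DEA rewards larger outputs. The default treatment replaces each
#' undesirable column `u` by the monotone decreasing translation
#' `u' = max(u) + kappa - u`, which reverses the ordering, keeps the column
#' on its original scale and preserves the dataset shape; under variable
#' returns to scale the radial input-oriented scores are invariant to such
#' output translations. Alternatively (`method = "input"`) undesirable
#' outputs are moved to the input side, the other common convention.
#'
#' @param ds a [dmu_data] object with `output_direction` flags set.
#' @param method `"translate"` (default) or `"input"`.
#' @param kappa translation offset added above the column maximum, in the
#'   column's own units (default 1); keeps transformed values strictly
#'   positive.
#' @return a new [dmu_data] object with desirable columns unchanged and the
#'   transformation recorded in `$transformed`. A zero-range undesirable
#'   column becomes the constant `kappa`, with a warning.
#' @export
transform_undesirable <- function(ds, method = c("translate", "input"),
                                  kappa = 1) {
  stopifnot(inherits(ds, "dmu_data"), kappa > 0)
  method <- match.arg(method)
  und <- which(ds$output_direction == "undesirable")
  if (!length(und)) {
    ds$transformed <- list(method = "none", columns = character(0))
    return(ds)
  }
  if (!is.null(ds$transformed)) stop("undesirable outputs already transformed")
  cols <- colnames(ds$Y)[und]
  if (method == "translate") {
    for (j in und) {
      u <- ds$Y[, j]
      if (max(u) - min(u) <= 0) {
        warning("undesirable output '", colnames(ds$Y)[j],
                "' has zero range; transformed column is the constant ", kappa)
      }
      ds$Y[, j] <- max(u) + kappa - u
    }
  } else {
    moved <- ds$Y[, und, drop = FALSE]
    if (any(moved <= 0)) {
      # inputs must be strictly positive; shift zero cells by kappa
      moved <- moved + ifelse(apply(moved, 2, min) <= 0, kappa, 0)[col(moved)]
    }
    ds$X <- cbind(ds$X, moved)
    ds$Y <- ds$Y[, -und, drop = FALSE]
    ds$output_direction <- ds$output_direction[-und]
    if (ncol(ds$Y) < 1L) stop("no desirable outputs left after moving ",
                              "undesirable outputs to the input side")
  }
  ds$transformed <- list(method = method, columns = cols, kappa = kappa)
  ds
}

#' Input-oriented slacks-based measure (SBM) efficiency of one DMU
#'
#' Solves the input-oriented SBM program for DMU `o`:
#' minimise `rho = 1 - (1/m) * sum_i s-_i / x_io` subject to
#' `X'lambda + s- = x_o`, `Y'lambda >= y_o`, `lambda >= 0` (and
#' `sum(lambda) = 1` under VRS). In the input orientation the objective is
#' linear in the slacks (no fractional program arises), so a single LP
#' suffices. Unlike the radial score, rho penalises every individual input
#' excess, so it detects mix inefficiency that radial models miss:
#' `rho <= theta` always, with equality only when the radial projection has
#' no residual slacks.
#'
#' @inheritParams solve_radial
#' @return a list of class `"dea_solution"` with `model = "sbm"`, elements
#'   `rho`, `lambda`, `input_slacks`, `reference_set`, `fully_efficient`
#'   (`rho = 1` up to tolerance).
#' @export
solve_sbm <- function(ds, o, rts = c("crs", "vrs"), control = dea_control()) {
  rts <- match.arg(rts)
  .require_transformed(ds)
  o <- .resolve_dmu(ds, o)
  X <- ds$X; Y <- ds$Y
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  # Variables: (lambda_1..n, s-_1..m); maximise sum_i s-_i / x_io.
  A <- rbind(cbind(t(X), diag(m)),
             cbind(t(Y), matrix(0, s, m)))
  dir <- c(rep("==", m), rep(">=", s))
  rhs <- c(X[o, ], Y[o, ])
  if (rts == "vrs") {
    A <- rbind(A, c(rep(1, n), rep(0, m)))
    dir <- c(dir, "==")
    rhs <- c(rhs, 1)
  }
  obj <- c(rep(0, n), 1 / X[o, ])
  sol <- solve_lp(obj, A, dir, rhs, maximize = TRUE,
                  tol = control$tolerance * 1e-2, feas_tol = control$tolerance)
  if (sol$status != "optimal") {
    stop("SBM LP ", sol$status, " for DMU ", ds$dmu_ids[o], " (invalid data?)")
  }
  rho <- max(0, min(1, 1 - sol$objval / m))
  lambda <- sol$x[seq_len(n)]
  s_in <- sol$x[n + seq_len(m)]
  names(lambda) <- ds$dmu_ids
  names(s_in) <- colnames(X)
  structure(list(dmu = ds$dmu_ids[o], model = "sbm", rts = rts, rho = rho,
                 lambda = lambda, input_slacks = s_in,
                 reference_set = ds$dmu_ids[lambda > control$efficiency_tol],
                 fully_efficient = rho >= 1 - control$efficiency_tol),
            class = "dea_solution")
}

#' Super-efficiency SBM score of one DMU
#'
#' Ranks SBM-efficient DMUs by re-solving efficiency with the evaluated unit
#' excluded from the reference set, which allows scores above 1: minimise
#' `(1/m) * sum_i xbar_i / x_io` subject to `xbar >= X'lambda` over the
#' remaining DMUs, `Y'lambda >= y_o`, `xbar >= x_o`, `lambda >= 0` (and
#' `sum(lambda) = 1` under VRS). For an inefficient DMU (rho < 1) the
#' super-score is defined as rho itself, so the combined score ranks all
#' DMUs on one scale. Under VRS the exclusion can leave the program
#' infeasible (or empty when n = 1); the score is then `Inf` with a warning,
#' the conventional sentinel for an unbeatable unit.
#'
#' @inheritParams solve_radial
#' @param sbm optional precomputed [solve_sbm()] solution for DMU `o`.
#' @return a single numeric super-efficiency score (`>= 1` for efficient
#'   DMUs, `= rho` for inefficient ones, possibly `Inf` under VRS).
#' @export
solve_super_sbm <- function(ds, o, rts = c("crs", "vrs"),
                            control = dea_control(), sbm = NULL) {
  rts <- match.arg(rts)
  .require_transformed(ds)
  o <- .resolve_dmu(ds, o)
  if (is.null(sbm)) sbm <- solve_sbm(ds, o, rts, control)
  if (sbm$rho < 1 - control$efficiency_tol) return(sbm$rho)
  X <- ds$X; Y <- ds$Y
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  if (n == 1L) {
    warning("reference set is empty after excluding DMU ", ds$dmu_ids[o],
            "; super-efficiency undefined, returning Inf")
    return(Inf)
  }
  keep <- setdiff(seq_len(n), o)
  nk <- length(keep)
  # Variables: (lambda_keep, t) with t = xbar - x_o >= 0.
  A <- rbind(cbind(t(X[keep, , drop = FALSE]), -diag(m)),   # X'l - t <= x_o
             cbind(t(Y[keep, , drop = FALSE]), matrix(0, s, m)))
  dir <- c(rep("<=", m), rep(">=", s))
  rhs <- c(X[o, ], Y[o, ])
  if (rts == "vrs") {
    A <- rbind(A, c(rep(1, nk), rep(0, m)))
    dir <- c(dir, "==")
    rhs <- c(rhs, 1)
  }
  obj <- c(rep(0, nk), 1 / X[o, ])
  sol <- solve_lp(obj, A, dir, rhs, maximize = FALSE,
                  tol = control$tolerance * 1e-2, feas_tol = control$tolerance)
  if (sol$status != "optimal") {
    warning("super-SBM program ", sol$status, " for DMU ", ds$dmu_ids[o],
            " after exclusion; returning Inf")
    return(Inf)
  }
  max(1, 1 + sol$objval / m)
}

#' Rank DMUs by SBM and super-SBM scores
#'
#' Orders all DMUs on one scale: efficient DMUs by their super-efficiency
#' score (descending), inefficient DMUs by rho (descending), ties broken by
#' DMU order in the dataset. Since super-scores are >= 1 >= rho, every
#' efficient DMU outranks every inefficient one.
#'
#' @param dmu character vector of DMU ids.
#' @param score numeric vector of combined scores (super-score for efficient
#'   DMUs, rho otherwise), same length.
#' @return integer ranks (1 = best), same order as `dmu`.
#' @export
rank_dmus <- function(dmu, score) {
  stopifnot(length(dmu) == length(score))
  ord <- order(-score, seq_along(score))
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  rank
}
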