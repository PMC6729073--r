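#' Solver configuration for the DEA programs
#'
#' @param tolerance LP pivot/feasibility tolerance.
#' @param efficiency_tol tolerance for treating a score as exactly one.
#' @param slack_phase run the second (slack-maximising) phase after the
#'   radial phase; on by default, so that reported slacks are the
#'   lexicographic maxima and "fully efficient" means radial score one with
#'   all slacks zero.
#' @return a list of class `"dea_control"`.
#' @export
dea_control <- function(tolerance = 1e-7, efficiency_tol = 1e-6,
                        slack_phase = TRUE) {
  stopifnot(tolerance > 0, efficiency_tol > 0)
  structure(list(tolerance = tolerance, efficiency_tol = efficiency_tol,
                 slack_phase = slack_phase), class = "dea_control")
}

# Ensure undesirable outputs were transformed before a solve.
.require_transformed <- function(ds) {
  if (any(ds$output_direction == "undesirable") && is.null(ds$transformed)) {
    stop("dataset has undesirable outputs; call transform_undesirable() first")
  }
  ds
}

#' Input-oriented radial (CCR/BCC) efficiency of one DMU
#'
#' Solves the input-oriented envelopment program for DMU `o`:
#' minimise theta subject to `X'lambda + s- = theta * x_o`,
#' `Y'lambda - s+ = y_o`, `lambda >= 0` (and `sum(lambda) = 1` under variable
#' returns to scale, the BCC model). A second phase fixes the optimal theta
#' and maximises the total slack, so slacks are the lexicographic maxima and
#' the non-Archimedean epsilon of the textbook single-stage form is never
#' given a numeric value. A DMU is fully (strongly) efficient iff theta = 1
#' and all phase-2 slacks are zero.
#'
#' @param ds a [dmu_data] object (undesirable outputs already transformed).
#' @param o DMU index (1-based) or id.
#' @param rts `"crs"` (CCR) or `"vrs"` (BCC).
#' @param control a [dea_control()] list.
#' @return a list of class `"dea_solution"`: `dmu`, `model = "radial"`, `rts`,
#'   `theta` (efficiency score in (0,1]), `lambda` (intensity weights, named by
#'   DMU), `input_slacks`, `output_slacks`, `reference_set` (ids with
#'   lambda above tolerance), `fully_efficient`.
#' @export
solve_radial <- function(ds, o, rts = c("crs", "vrs"), control = dea_control()) {
  rts <- match.arg(rts)
  .require_transformed(ds)
  o <- .resolve_dmu(ds, o)
  X <- ds$X; Y <- ds$Y
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  # Phase 1 variables: (theta, lambda_1..n)
  A <- rbind(cbind(-X[o, ], t(X)),          # X'lambda - theta x_o <= 0
             cbind(0, t(Y)))                # Y'lambda >= y_o
  dir <- c(rep("<=", m), rep(">=", s))
  rhs <- c(rep(0, m), Y[o, ])
  if (rts == "vrs") {
    A <- rbind(A, c(0, rep(1, n)))
    dir <- c(dir, "==")
    rhs <- c(rhs, 1)
  }
  sol <- solve_lp(c(1, rep(0, n)), A, dir, rhs, maximize = FALSE,
                  tol = control$tolerance * 1e-2, feas_tol = control$tolerance)
  if (sol$status != "optimal") {
    stop("radial envelopment LP ", sol$status, " for DMU ", ds$dmu_ids[o],
         " (invalid data?)")
  }
  theta <- sol$objval
  lambda <- sol$x[-1]
  s_in <- pmax(theta * X[o, ] - as.numeric(t(X) %*% lambda), 0)
  s_out <- pmax(as.numeric(t(Y) %*% lambda) - Y[o, ], 0)

  if (control$slack_phase) {
    # Phase 2 variables: (lambda, s-, s+); maximise total slack at theta*.
    A2 <- rbind(cbind(t(X), diag(m), matrix(0, m, s)),
                cbind(t(Y), matrix(0, s, m), -diag(s)))
    dir2 <- rep("==", m + s)
    rhs2 <- c(theta * X[o, ], Y[o, ])
    if (rts == "vrs") {
      A2 <- rbind(A2, c(rep(1, n), rep(0, m + s)))
      dir2 <- c(dir2, "==")
      rhs2 <- c(rhs2, 1)
    }
    obj2 <- c(rep(0, n), rep(1, m + s))
    sol2 <- solve_lp(obj2, A2, dir2, rhs2, maximize = TRUE,
                     tol = control$tolerance * 1e-2,
                     feas_tol = control$tolerance)
    if (sol2$status == "optimal") {
      lambda <- sol2$x[seq_len(n)]
      s_in <- sol2$x[n + seq_len(m)]
      s_out <- sol2$x[n + m + seq_len(s)]
    }
  }
  names(lambda) <- ds$dmu_ids
  names(s_in) <- colnames(X)
  names(s_out) <- colnames(Y)
  eff <- theta >= 1 - control$efficiency_tol &&
    all(c(s_in, s_out) <= sqrt(control$tolerance))
  structure(list(dmu = ds$dmu_ids[o], model = "radial", rts = rts,
                 theta = min(theta, 1),
                 lambda = lambda, input_slacks = s_in, output_slacks = s_out,
                 reference_set = ds$dmu_ids[lambda > control$efficiency_tol],
                 fully_efficient = eff),
            class = "dea_solution")
}

.resolve_dmu <- function(ds, o) {
  if (is.character(o)) {
    i <- match(o, ds$dmu_ids)
    if (is.na(i)) stop("unknown DMU id: ", o)
    return(i)
  }
  o <- as.integer(o)
  if (o < 1L || o > nrow(ds$X)) stop("DMU index out of range: ", o)
  o
}

#' @export
print.dea_solution <- function(x, ...) {
  score <- if (x$model == "radial") x$theta else x$rho
  cat(sprintf("%s DEA solution (%s), DMU %s: score %.4f%s\n",
              toupper(x$model), toupper(x$rts), x$dmu, score,
              if (isTRUE(x$fully_efficient)) " (fully efficient)" else ""))
  if (length(x$reference_set)) {
    cat("reference set:", paste(x$reference_set, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Decompose technical efficiency into pure technical and scale efficiency
#'
#' For one DMU solved under both constant (CCR) and variable (BCC) returns to
#' scale: TE is the CCR score, PTE the BCC score, and SE = TE / PTE, the loss
#' attributable to operating away from the most productive scale size. The
#' CRS frontier envelops the VRS frontier, so SE <= 1 up to tolerance.
#'
#' @param ccr,bcc [solve_radial()] solutions for the same DMU under
#'   `rts = "crs"` and `rts = "vrs"` respectively.
#' @return named numeric vector `c(te, pte, se)`.
#' @export
decompose_efficiency <- function(ccr, bcc) {
  stopifnot(inherits(ccr, "dea_solution"), inherits(bcc, "dea_solution"))
  if (!identical(ccr$dmu, bcc$dmu)) {
    stop("CCR and BCC solutions are for different DMUs (",
         ccr$dmu, " vs ", bcc$dmu, ")")
  }
  if (ccr$rts != "crs" || bcc$rts != "vrs") {
    stop("expected a CRS solution and a VRS solution, in that order")
  }
  c(te = ccr$theta, pte = bcc$theta, se = ccr$theta / bcc$theta)
}

#' Classify returns to scale of one DMU
#'
#' Classifies the returns to scale at DMU `o` from the sum of optimal
#' intensity weights in the CCR model. Because the optimal lambda need not be
#' unique, the single-solution rule (sum < 1 increasing, sum > 1 decreasing)
#' is ill-defined; this function instead computes the minimum and maximum of
#' `sum(lambda)` over the whole CRS optimal face (two secondary LPs with
#' theta fixed at its optimum) and labels the DMU CRS when the interval
#' contains 1, IRS when its maximum is below 1, and DRS when its minimum is
#' above 1. The classification is deterministic and independent of which
#' optimal vertex the solver happens to return.
#'
#' @inheritParams solve_radial
#' @param theta optional precomputed CCR score for DMU `o`.
#' @return a list: `label` in `c("CRS","IRS","DRS")`, `sum_lambda_bounds`
#'   (the `[min, max]` interval), `theta`.
#' @export
classify_rts <- function(ds, o, control = dea_control(), theta = NULL) {
  .require_transformed(ds)
  o <- .resolve_dmu(ds, o)
  if (is.null(theta)) theta <- solve_radial(ds, o, "crs", control)$theta
  X <- ds$X; Y <- ds$Y
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  A <- rbind(t(X), t(Y))
  dir <- c(rep("<=", m), rep(">=", s))
  rhs <- c(theta * X[o, ], Y[o, ])
  obj <- rep(1, n)
  lo <- solve_lp(obj, A, dir, rhs, maximize = FALSE,
                 tol = control$tolerance * 1e-2, feas_tol = control$tolerance)
  hi <- solve_lp(obj, A, dir, rhs, maximize = TRUE,
                 tol = control$tolerance * 1e-2, feas_tol = control$tolerance)
  if (lo$status != "optimal") {
    stop("RTS bound LP ", lo$status, " for DMU ", ds$dmu_ids[o])
  }
  smin <- lo$objval
  smax <- if (hi$status == "optimal") hi$objval else Inf
  tol <- sqrt(control$tolerance)
  label <- if (smin > 1 + tol) "DRS" else if (smax < 1 - tol) "IRS" else "CRS"
  list(label = label, sum_lambda_bounds = c(min = smin, max = smax),
       theta = theta)
}
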