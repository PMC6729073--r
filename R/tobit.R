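#' Two-limit Tobit (censored-normal) regression
#'
#' Maximum-likelihood estimation of the censored-normal regression model
#' `y* = x'beta + e`, `e ~ N(0, sigma^2)`, observed as
#' `y = min(max(y*, lower), upper)`. Efficiency scores pile up at the upper
#' limit 1, so an ordinary linear regression of scores on covariates is
#' biased; the Tobit likelihood uses the normal density for interior
#' observations and the corresponding normal tail probability for
#' observations at either limit. (The score distribution is often described
#' as "truncated", but the estimator appropriate to scores observed at their
#' bound is the censored-normal one implemented here.)
#'
#' The likelihood is maximised by quasi-Newton (BFGS) iteration over
#' `(beta, log sigma)` from an ordinary least-squares start, with the
#' analytic gradient; standard errors come from the inverse observed
#' information evaluated at `(beta, sigma)`. An intercept-only null model is
#' fitted on the same data for the likelihood-ratio statistic and McFadden's
#' pseudo-R².
#'
#' @param formula model formula, e.g. `score ~ location + occupancy`.
#' @param data data frame holding the variables.
#' @param lower,upper censoring limits; defaults `(0, 1)` suit efficiency
#'   scores. Use `-Inf`/`Inf` to disable a limit (e.g. when regressing
#'   super-efficiency scores, which exceed 1).
#' @param limit_tol observations within `limit_tol` of a limit are treated
#'   as censored there.
#' @param maxit maximum BFGS iterations.
#' @return an object of class `"tobit"`: list with `coefficients`, `sigma`,
#'   `se` (for coefficients and sigma), `vcov`, `loglik`, `loglik_null`,
#'   `n`, `n_censored_lower`, `n_censored_upper`, `n_uncensored`, `df`
#'   (number of covariates excluding intercept), `converged`, `iterations`,
#'   `limits`, `call`, `terms`, `model`.
#' @seealso [lr_test()], [run_second_stage()], [summary.tobit()]
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(200)
#' y <- pmin(0.4 + 0.6 * x + rnorm(200, 0, 0.2), 1)
#' fit <- tobit(y ~ x, data.frame(x = x, y = y))
#' coef(fit)
tobit <- function(formula, data, lower = 0, upper = 1,
                  limit_tol = 1e-9, maxit = 500) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- tobit_fit(y, X, lower = lower, upper = upper,
                   limit_tol = limit_tol, maxit = maxit)
  fit$call <- cl
  fit$terms <- attr(mf, "terms")
  fit$model <- mf
  fit
}

# Negative log-likelihood and gradient over par = (beta, log sigma).
.tobit_nll <- function(par, y, X, lower, upper, int, lo, up) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  sigma <- exp(par[k + 1])
  xb <- as.numeric(X %*% beta)
  ll <- 0
  if (any(int)) {
    ll <- ll + sum(stats::dnorm((y[int] - xb[int]) / sigma, log = TRUE)) -
      sum(int) * log(sigma)
  }
  if (any(up)) ll <- ll + sum(stats::pnorm((xb[up] - upper) / sigma,
                                           log.p = TRUE))
  if (any(lo)) ll <- ll + sum(stats::pnorm((lower - xb[lo]) / sigma,
                                           log.p = TRUE))
  -ll
}

.tobit_grad <- function(par, y, X, lower, upper, int, lo, up) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  sigma <- exp(par[k + 1])
  xb <- as.numeric(X %*% beta)
  g_beta <- numeric(k)
  g_lsig <- 0
  if (any(int)) {
    z <- (y[int] - xb[int]) / sigma
    g_beta <- g_beta + as.numeric(crossprod(X[int, , drop = FALSE], z / sigma))
    g_lsig <- g_lsig + sum(z^2 - 1)
  }
  mills <- function(q) exp(stats::dnorm(q, log = TRUE) -
                           stats::pnorm(q, log.p = TRUE))
  if (any(up)) {
    z <- (xb[up] - upper) / sigma
    lam <- mills(z)
    g_beta <- g_beta + as.numeric(crossprod(X[up, , drop = FALSE], lam / sigma))
    g_lsig <- g_lsig - sum(lam * z)
  }
  if (any(lo)) {
    z <- (lower - xb[lo]) / sigma
    lam <- mills(z)
    g_beta <- g_beta - as.numeric(crossprod(X[lo, , drop = FALSE], lam / sigma))
    g_lsig <- g_lsig - sum(lam * z)
  }
  -c(g_beta, g_lsig)
}

#' Low-level two-limit Tobit fit
#'
#' Matrix interface behind [tobit()]; `X` must already contain any intercept
#' column.
#'
#' @param y numeric response vector.
#' @param X model matrix (n x k).
#' @inheritParams tobit
#' @param null_fit internal; skip fitting the intercept-only reference model.
#' @return see [tobit()].
#' @export
tobit_fit <- function(y, X, lower = 0, upper = 1, limit_tol = 1e-9,
                      maxit = 500, null_fit = FALSE) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  if (n != nrow(X)) stop("y and X disagree on n")
  if (n <= k + 2) stop("too few observations (n = ", n, ") for ", k,
                       " coefficients")
  qrX <- qr(X)
  if (qrX$rank < k) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop("collinear covariates: ", paste(drop_cols, collapse = ", "))
  }
  lo <- y <= lower + limit_tol
  up <- y >= upper - limit_tol
  int <- !lo & !up
  if (!any(int)) {
    stop("degenerate data: all ", n, " observations are censored; ",
         "the likelihood carries no information about sigma")
  }
  # OLS start (interior observations pin down the scale well enough).
  ols <- stats::lm.fit(X, pmin(pmax(y, lower), upper))
  s0 <- max(sqrt(mean(ols$residuals^2)), 1e-3)
  par0 <- c(ols$coefficients, log(s0))
  par0[is.na(par0)] <- 0
  ctrl <- list(maxit = maxit, reltol = 1e-12)
  nll <- function(p) .tobit_nll(p, y, X, lower, upper, int, lo, up)
  grd <- function(p) .tobit_grad(p, y, X, lower, upper, int, lo, up)
  opt <- stats::optim(par0, nll, grd, method = "BFGS", control = ctrl)
  if (opt$convergence != 0) {
    stop("Tobit likelihood maximisation failed to converge (optim code ",
         opt$convergence, ", ", opt$counts[["function"]],
         " evaluations, nll ", format(opt$value), ")")
  }
  beta <- opt$par[seq_len(k)]
  names(beta) <- colnames(X)
  sigma <- unname(exp(opt$par[k + 1]))
  # Observed information on the (beta, sigma) scale; differentiating the
  # analytic gradient keeps the Hessian accurate across parameter scales.
  nll_sig <- function(p) .tobit_nll(c(p[seq_len(k)], log(p[k + 1])),
                                    y, X, lower, upper, int, lo, up)
  grad_sig <- function(p) {
    g <- .tobit_grad(c(p[seq_len(k)], log(p[k + 1])),
                     y, X, lower, upper, int, lo, up)
    g[k + 1] <- g[k + 1] / p[k + 1]   # d/dsigma = (1/sigma) d/dlog sigma
    g
  }
  par_hat <- c(beta, sigma)
  H <- stats::optimHess(par_hat, nll_sig, grad_sig,
                        control = list(ndeps = pmax(abs(par_hat), 1e-3) * 1e-4))
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k + 1, k + 1))
  dimnames(vc) <- list(c(names(beta), "sigma"), c(names(beta), "sigma"))
  se <- sqrt(pmax(diag(vc), 0))
  loglik <- -opt$value
  loglik_null <- if (null_fit) {
    NA_real_
  } else if (k == 1L && all(X == X[1, 1])) {
    loglik
  } else {
    nf <- tobit_fit(y, matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                    lower = lower, upper = upper, limit_tol = limit_tol,
                    maxit = maxit, null_fit = TRUE)
    nf$loglik
  }
  structure(list(coefficients = beta, sigma = sigma,
                 se = se[seq_len(k)], se_sigma = se[k + 1], vcov = vc,
                 loglik = loglik, loglik_null = loglik_null,
                 n = n, n_censored_lower = sum(lo), n_censored_upper = sum(up),
                 n_uncensored = sum(int), df = k - 1L,
                 converged = TRUE, iterations = opt$counts[["function"]],
                 limits = c(lower = lower, upper = upper),
                 start_loglik = -.tobit_nll(par0, y, X, lower, upper,
                                            int, lo, up)),
            class = "tobit")
}

#' @export
coef.tobit <- function(object, ...) object$coefficients

#' @export
vcov.tobit <- function(object, ...) object$vcov

#' @export
logLik.tobit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            nobs = object$n, class = "logLik")
}

#' @export
confint.tobit <- function(object, parm, level = 0.95, ...) {
  est <- c(object$coefficients, sigma = object$sigma)
  se <- c(object$se, object$se_sigma)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - z * se, est + z * se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.tobit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    X <- stats::model.matrix(object$terms, object$model)
  } else {
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
  }
  as.numeric(X %*% object$coefficients)
}

#' @export
residuals.tobit <- function(object, ...) {
  y <- stats::model.response(object$model)
  y - predict(object)
}

#' @export
print.tobit <- function(x, digits = 4, ...) {
  cat("Two-limit Tobit regression, limits [",
      x$limits[["lower"]], ", ", x$limits[["upper"]], "]\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("sigma %.4f | logLik %.3f | n %d (%d lower-, %d upper-censored)\n",
              x$sigma, x$loglik, x$n, x$n_censored_lower, x$n_censored_upper))
  invisible(x)
}

#' Summary of a Tobit fit
#'
#' Per-coefficient estimate, standard error, Wald z and p-value (normal
#' reference), 95% confidence interval; plus the scale, censoring counts,
#' McFadden pseudo-R² (`1 - loglik / loglik_null`) and the likelihood-ratio
#' statistic against the intercept-only model.
#'
#' @param object a [tobit] fit.
#' @param ... unused.
#' @return a list of class `"summary.tobit"` with a `table` data frame and
#'   scalar fit statistics.
#' @export
summary.tobit <- function(object, ...) {
  z <- object$coefficients / object$se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- confint.tobit(object)
  tab <- data.frame(estimate = object$coefficients, se = object$se,
                    z = z, p = p,
                    ci_lo = ci[seq_along(z), 1], ci_hi = ci[seq_along(z), 2])
  lr <- 2 * (object$loglik - object$loglik_null)
  structure(list(table = tab, sigma = object$sigma,
                 se_sigma = object$se_sigma,
                 loglik = object$loglik, loglik_null = object$loglik_null,
                 pseudo_r2 = 1 - object$loglik / object$loglik_null,
                 lr = lr, df = object$df,
                 lr_p = stats::pchisq(lr, max(object$df, 1), lower.tail = FALSE),
                 n = object$n, n_censored_lower = object$n_censored_lower,
                 n_censored_upper = object$n_censored_upper),
            class = "summary.tobit")
}

#' @export
print.summary.tobit <- function(x, digits = 4, ...) {
  tab <- x$table
  tab[] <- lapply(tab, signif, digits)
  print(tab)
  cat(sprintf("sigma %.4f (se %.4f); n %d, censored %d lower / %d upper\n",
              x$sigma, x$se_sigma, x$n, x$n_censored_lower,
              x$n_censored_upper))
  cat(sprintf("logLik %.3f (null %.3f); LR %.3f on %d df, p %.4g; pseudo-R2 %.4f\n",
              x$loglik, x$loglik_null, x$lr, x$df, x$lr_p, x$pseudo_r2))
  invisible(x)
}

#' Likelihood-ratio test of a Tobit fit against the intercept-only model
#'
#' @param fit a [tobit] fit (its intercept-only reference model is fitted on
#'   identical data and limits at fit time).
#' @return a list `lr` (the statistic `2 * (loglik - loglik_null)`, >= 0 up
#'   to numerical noise), `df` (number of covariates), `p` (chi-square upper
#'   tail).
#' @export
lr_test <- function(fit) {
  stopifnot(inherits(fit, "tobit"))
  if (is.na(fit$loglik_null)) stop("fit carries no null model")
  lr <- max(2 * (fit$loglik - fit$loglik_null), 0)
  df <- max(fit$df, 1L)
  list(lr = lr, df = fit$df,
       p = stats::pchisq(lr, df, lower.tail = FALSE))
}

#' Second-stage regression of efficiency scores on covariates
#'
#' Joins a per-DMU efficiency table with a covariate table on DMU id and
#' fits a two-limit Tobit of the chosen score (BCC pure technical efficiency
#' or SBM efficiency) on all covariate columns. Binary covariates should be
#' coded 0/1 and shares/rates as fractions or percentages, consistently.
#'
#' @param eff data frame with a `dmu` column and score columns (`pte`
#'   and/or `sbm`), e.g. [efficiency_table()] output.
#' @param covariates data frame with a `dmu` column and the regressors.
#' @param which_score `"bcc"` (uses the `pte` column) or `"sbm"`.
#' @param lower,upper censoring limits passed to [tobit()].
#' @return a [tobit] fit.
#' @export
run_second_stage <- function(eff, covariates, which_score = c("bcc", "sbm"),
                             lower = 0, upper = 1) {
  which_score <- match.arg(which_score)
  if (!"dmu" %in% names(eff) || !"dmu" %in% names(covariates)) {
    stop("both tables need a 'dmu' id column")
  }
  miss <- setdiff(as.character(eff$dmu), as.character(covariates$dmu))
  if (length(miss)) {
    stop("covariate table is missing DMUs: ", paste(miss, collapse = ", "))
  }
  score_col <- if (which_score == "bcc") "pte" else "sbm"
  if (!score_col %in% names(eff)) stop("efficiency table has no '",
                                       score_col, "' column")
  idx <- match(as.character(eff$dmu), as.character(covariates$dmu))
  dat <- cbind(data.frame(.score = eff[[score_col]]),
               covariates[idx, setdiff(names(covariates), "dmu"),
                          drop = FALSE])
  f <- stats::as.formula(paste(".score ~",
                               paste(setdiff(names(dat), ".score"),
                                     collapse = " + ")))
  tobit(f, dat, lower = lower, upper = upper)
}
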