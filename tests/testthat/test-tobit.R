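test_that("without censoring the fit collapses to Gaussian regression", {
  set.seed(61)
  n <- 300
  x <- runif(n)
  y <- 0.2 + 0.5 * x + rnorm(n, 0, 0.1)
  dat <- data.frame(x = x, y = y)
  fit <- tobit(y ~ x, dat, lower = -Inf, upper = Inf)
  ols <- lm(y ~ x, dat)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  # MLE scale (divisor n, not n - k)
  expect_equal(fit$sigma, sqrt(mean(residuals(ols)^2)), tolerance = 1e-6)
  expect_identical(fit$n_censored_lower + fit$n_censored_upper, 0L)
})

test_that("the censored likelihood matches survreg on the same data", {
  skip_if_not_installed("survival")
  sim <- simulate_tobit(800, beta = c(0.3, 0.7), sigma = 0.25,
                        limits = c(0, 1), seed = 62)
  fit <- tobit(score ~ x1, sim$data, 0, 1)
  y <- sim$data$score
  t1 <- ifelse(y <= 0, NA, y)
  t2 <- ifelse(y >= 1, NA, y)
  sv <- survival::survreg(
    survival::Surv(t1, t2, type = "interval2") ~ x1,
    data = sim$data, dist = "gaussian")
  expect_equal(unname(coef(fit)), unname(coef(sv)), tolerance = 1e-5)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-5)
})

test_that("parameters of a censored DGP are recovered within 3 SE", {
  sim <- simulate_tobit(5000, beta = c(0.4, 0.6), sigma = 0.2,
                        limits = c(-Inf, 1), seed = 63)
  fit <- tobit(score ~ x1, sim$data, lower = -Inf, upper = 1)
  est <- c(coef(fit), fit$sigma)
  se <- c(fit$se, fit$se_sigma)
  expect_true(all(abs(est - c(0.4, 0.6, 0.2)) <= 3 * se))
  expect_gt(fit$n_censored_upper, 0)
  expect_identical(fit$n_censored_lower + fit$n_censored_upper +
                     fit$n_uncensored, fit$n)
})

test_that("estimation bias shrinks as the sample grows", {
  err <- vapply(c(100, 1000, 10000), function(n) {
    sim <- simulate_tobit(n, beta = c(0.4, 0.6), sigma = 0.2,
                          limits = c(0, 1), seed = 64)
    fit <- tobit(score ~ x1, sim$data, 0, 1)
    sum(abs(coef(fit) - c(0.4, 0.6)))
  }, numeric(1))
  expect_lt(err[3], err[1])
})

test_that("degenerate and ill-posed inputs are refused", {
  dat <- data.frame(x = runif(30), y = rep(1, 30))
  expect_error(tobit(y ~ x, dat), "censored")
  set.seed(65)
  d2 <- data.frame(x1 = runif(30))
  d2$x2 <- 2 * d2$x1          # exactly collinear
  d2$y <- pmin(0.5 + d2$x1 + rnorm(30, 0, 0.1), 1)
  expect_error(tobit(y ~ x1 + x2, d2), "collinear.*x2")
  expect_error(tobit_fit(runif(4), cbind(1, runif(4), runif(4))), "too few")
})

test_that("coefficients are equivariant to covariate rescaling", {
  sim <- simulate_tobit(400, beta = c(0.3, 0.5), sigma = 0.2,
                        limits = c(0, 1), seed = 66)
  f1 <- tobit(score ~ x1, sim$data, 0, 1)
  d2 <- sim$data
  d2$x1 <- d2$x1 * 100
  f2 <- tobit(score ~ x1, d2, 0, 1)
  expect_equal(coef(f2)[["x1"]], coef(f1)[["x1"]] / 100, tolerance = 1e-6)
  expect_equal(f2$se[["x1"]], f1$se[["x1"]] / 100, tolerance = 1e-4)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-6)
})

test_that("likelihood-ratio machinery is coherent", {
  sim <- simulate_tobit(300, beta = c(0.5, 0.4), sigma = 0.2,
                        limits = c(0, 1), seed = 67)
  fit <- tobit(score ~ x1, sim$data, 0, 1)
  lt <- lr_test(fit)
  expect_gte(lt$lr, 0)
  expect_identical(lt$df, 1L)
  expect_equal(lt$lr, 2 * (fit$loglik - fit$loglik_null), tolerance = 1e-8)
  # optimiser never ends below its start or the nested null
  expect_gte(fit$loglik, fit$start_loglik - 1e-8)
  expect_gte(fit$loglik, fit$loglik_null - 1e-8)
  # intercept-only model tested against itself
  null_fit <- tobit(score ~ 1, sim$data, 0, 1)
  expect_equal(lr_test(null_fit)$lr, 0, tolerance = 1e-6)
  s <- summary(fit)
  # McFadden's ratio is a proportion only while both log-likelihoods are
  # negative; densities above one (small sigma) push log-likelihoods positive
  if (fit$loglik_null < 0 && fit$loglik < 0) {
    expect_true(s$pseudo_r2 >= 0 && s$pseudo_r2 < 1)
  } else {
    expect_gte(s$pseudo_r2, 0)
  }
})

test_that("second stage joins on DMU id and reports both score choices", {
  set.seed(68)
  n <- 60
  occ <- runif(n)
  scores <- pmin(pmax(0.45 + 0.5 * occ + rnorm(n, 0, 0.15), 0), 1)
  eff <- data.frame(dmu = as.character(1:n), pte = scores,
                    sbm = pmin(pmax(scores - 0.1, 0.01), 1))
  covs <- data.frame(dmu = as.character(1:n), occupancy = occ)
  fb <- run_second_stage(eff, covs, "bcc")
  fs <- run_second_stage(eff, covs, "sbm")
  expect_s3_class(fb, "tobit")
  expect_false(isTRUE(all.equal(coef(fb), coef(fs))))
  expect_gt(coef(fb)[["occupancy"]], 0)
  # unmatched ids are named
  expect_error(run_second_stage(eff, covs[-3, ], "bcc"), "missing DMUs: 3")
})

test_that("an occupancy effect planted in the DGP is detected repeatedly", {
  hits <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    sim <- simulate_tobit(200, beta = c(0.3, 0.6), sigma = 0.2,
                          limits = c(0, 1), seed = 7000 + r)
    names(sim$data)[2] <- "occupancy"
    eff <- data.frame(dmu = as.character(1:200), pte = sim$data$score,
                      sbm = sim$data$score)
    covs <- data.frame(dmu = as.character(1:200),
                       occupancy = sim$data$occupancy)
    fit <- run_second_stage(eff, covs, "bcc")
    s <- summary(fit)$table
    if (s["occupancy", "estimate"] > 0 && s["occupancy", "p"] < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / reps, 0.9)
})
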