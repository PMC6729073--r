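#' Simulate a DMU dataset with known true efficiency
#'
#' Builds a constant-returns technology from a single reference
#' input-output mix ("ray" technology): frontier DMUs are positive scalings
#' of one base unit and are efficient by construction; each remaining DMU is
#' a frontier point with all inputs multiplied by its inefficiency factor
#' `f >= 1`, so its true input-oriented CRS technical efficiency is exactly
#' `1 / f`. This is the one construction under which the ground truth is
#' closed-form, which is what makes the generator usable as an oracle for
#' solver-recovery tests; a convex multi-mix (VRS) frontier would leave the
#' truth solver-defined and is deliberately not offered.
#'
#' @param n_dmu number of DMUs.
#' @param m,s numbers of inputs and outputs.
#' @param factors numeric vector of inefficiency factors (`>= 1`), recycled
#'   to `n_dmu`; a factor of 1 puts the DMU on the frontier. Default: first
#'   half on the frontier, rest uniform in (1, 2].
#' @param seed RNG seed; fixed seed gives bitwise-identical output.
#' @param noise_sd log-normal jitter applied to the frontier scale of each
#'   DMU (not to the factor), so DMUs differ in size; does not perturb the
#'   ground truth.
#' @return a list: `data` (a [dmu_data] object) and `true_te` (numeric,
#'   `1 / factors`).
#' @export
simulate_frontier <- function(n_dmu, m = 2, s = 2, factors = NULL,
                              seed = 1, noise_sd = 0.25) {
  set.seed(seed)
  if (is.null(factors)) {
    factors <- c(rep(1, ceiling(n_dmu / 2)),
                 1 + stats::runif(floor(n_dmu / 2)))
  }
  factors <- rep_len(factors, n_dmu)
  if (any(factors < 1)) stop("inefficiency factors must be >= 1")
  base_x <- stats::runif(m, 1, 10)
  base_y <- stats::runif(s, 1, 10)
  scale <- exp(stats::rnorm(n_dmu, 0, noise_sd))
  X <- outer(scale * factors, base_x)
  Y <- outer(scale, base_y)
  colnames(X) <- paste0("input_", seq_len(m))
  colnames(Y) <- paste0("output_", seq_len(s))
  list(data = dmu_data(X, Y), true_te = 1 / factors)
}

#' Simulate a facility dataset resembling the 32-LTCF study
#'
#' Draws each of the six input and six output indicators from a log-normal
#' body matched to the published per-column mean and standard deviation
#' (strong right skew: several columns have SD above their mean), truncated
#' to the published range. Undesirable quality outputs (fall rate,
#' unhandled-complaint rate, accident incidence) are shifted off zero by a
#' small offset before the log-normal draw and kept on the printed 0-100
#' percentage scale. Covariates mirror the published facility structure:
#' ownership about 7 public / 25 private per 32, location about 22 urban /
#' 10 rural, occupancy centred near 47%, plus staffing-quality covariates
#' (share of staff working >= 2 years, annual trainings, share of
#' college-graduate caregivers).
#'
#' @param n number of facilities; below 24 the adequacy rule of thumb for a
#'   6-input/6-output model fails downstream, so a warning is raised.
#' @param seed RNG seed.
#' @return a [dmu_data] object with 6 inputs, 6 outputs (quality rates
#'   flagged undesirable) and a covariate table (`ownership_private`,
#'   `location_urban`, `occupancy`, `share_tenure2y`, `trainings`,
#'   `share_college`).
#' @export
simulate_ltcf <- function(n = 32, seed = 1) {
  if (n < 24) warning("n < 24: fails the adequacy rule of thumb for ",
                      "a 6-input/6-output model")
  set.seed(seed)
  mom <- ltcf_moments()
  draw <- function(row) {
    mu <- row$mean; sdv <- row$sd
    off <- if (row$min <= 0) 0.5 * max(sdv, 0.1) else 0   # shift off zero
    m2 <- mu + off
    cv2 <- (sdv / m2)^2
    sl <- sqrt(log1p(cv2))
    ml <- log(m2) - sl^2 / 2
    x <- stats::rlnorm(n, ml, sl) - off
    lo <- max(row$min, if (row$role == "input") 1e-3 else 0)
    pmin(pmax(x, lo), row$max)
  }
  vals <- lapply(seq_len(nrow(mom)), function(i) draw(mom[i, ]))
  names(vals) <- mom$variable
  X <- do.call(cbind, vals[mom$variable[mom$role == "input"]])
  Y <- do.call(cbind, vals[mom$variable[mom$role == "output"]])
  # headcounts and beds are integers
  count_in <- mom$variable[mom$role == "input" & mom$unit != "million yuan"]
  X[, count_in] <- pmax(round(X[, count_in]), 1)
  count_out <- mom$variable[mom$role == "output" & mom$unit == "residents"]
  Y[, count_out] <- round(Y[, count_out])
  covariates <- data.frame(
    dmu = as.character(seq_len(n)),
    ownership_private = stats::rbinom(n, 1, 25 / 32),
    location_urban = stats::rbinom(n, 1, 22 / 32),
    occupancy = stats::rbeta(n, 2.2, 2.5),           # mean ~ 0.47
    share_tenure2y = stats::rbeta(n, 3, 2),
    trainings = stats::rpois(n, 6),
    share_college = stats::rbeta(n, 1.5, 4))
  dmu_data(X, Y, dmu_ids = covariates$dmu,
           output_direction = ifelse(
             mom$direction[mom$role == "output"] == "undesirable",
             "undesirable", "desirable"),
           covariates = covariates[-1])
}

#' Simulate censored efficiency scores with known regression truth
#'
#' Generates `score = clamp(Xc beta + e, limits)` with `e ~ N(0, sigma^2)`,
#' censoring applied exactly at the limits, for Tobit parameter-recovery
#' tests. Covariates are drawn uniform on (0, 1) unless supplied.
#'
#' @param n observations.
#' @param beta coefficient vector; the first element is the intercept.
#' @param sigma error standard deviation (`sigma = 0` gives deterministic
#'   scores).
#' @param limits length-2 numeric `(lower, upper)`; use `c(-Inf, Inf)` for
#'   no censoring.
#' @param covariates optional matrix (n x (length(beta) - 1)).
#' @param seed RNG seed.
#' @return a list: `data` (data frame with `score` and covariate columns),
#'   `truth` (list `beta`, `sigma`, `limits`), `latent` (the uncensored
#'   scores), `censored` (factor: lower/none/upper).
#' @export
simulate_tobit <- function(n, beta = c(0.4, 0.6), sigma = 0.2,
                           limits = c(0, 1), covariates = NULL, seed = 1) {
  set.seed(seed)
  k <- length(beta) - 1L
  if (is.null(covariates)) {
    covariates <- matrix(stats::runif(n * k), n, k)
  }
  covariates <- as.matrix(covariates)
  if (k > 0 && is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("x", seq_len(k))
  }
  latent <- as.numeric(cbind(1, covariates) %*% beta) +
    stats::rnorm(n, 0, sigma)
  score <- pmin(pmax(latent, limits[1]), limits[2])
  cens <- factor(ifelse(latent <= limits[1], "lower",
                        ifelse(latent >= limits[2], "upper", "none")),
                 levels = c("lower", "none", "upper"))
  dat <- data.frame(score = score, covariates)
  list(data = dat,
       truth = list(beta = beta, sigma = sigma, limits = limits),
       latent = latent, censored = cens)
}
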