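#' Full DEA efficiency analysis of a DMU dataset
#'
#' Fits the complete first-stage benchmarking model to every DMU:
#' input-oriented radial scores under constant (CCR) and variable (BCC)
#' returns to scale with two-phase slack maximisation, the decomposition
#' TE = PTE x SE, returns-to-scale classification from the sum-of-intensities
#' interval, the input-oriented slacks-based measure (SBM), and — for
#' SBM-efficient units — the super-efficiency SBM score used to rank them.
#' Undesirable outputs are transformed up front (see
#' [transform_undesirable()]).
#'
#' The per-DMU results form the familiar published layout: TE (CCR), PTE
#' (BCC), SE, RTS label, SBM efficiency and rank.
#'
#' @param data a [dmu_data] object.
#' @param sbm_rts returns-to-scale assumption for the SBM/super-SBM stage;
#'   defaults to `"vrs"`, matching the convention of comparing the SBM score
#'   against the BCC frontier.
#' @param undesirable treatment of undesirable outputs, passed to
#'   [transform_undesirable()].
#' @param super compute super-efficiency SBM scores for efficient DMUs
#'   (default `TRUE`).
#' @param control a [dea_control()] list.
#' @return an object of class `"dea"`: a list with
#'   \describe{
#'     \item{results}{data frame with one row per DMU: `dmu`, `te`, `pte`,
#'       `se`, `rts`, `sbm`, `super_sbm`, `rank`.}
#'     \item{solutions}{per-DMU list of the underlying `ccr`, `bcc`, `sbm`
#'       solution objects and the RTS interval.}
#'     \item{data}{the (transformed) dataset the programs were solved on.}
#'     \item{control}{the solver settings used.}
#'   }
#' @seealso [summary.dea()], [efficiency_table()], [adjustment_table()]
#' @export
#' @examples
#' d <- dmu_data(inputs = cbind(x = c(1, 2, 4)),
#'               outputs = cbind(y = c(1, 4, 6)))
#' fit <- dea(d)
#' fit$results
dea <- function(data, sbm_rts = c("vrs", "crs"),
                undesirable = c("translate", "input"),
                super = TRUE, control = dea_control()) {
  stopifnot(inherits(data, "dmu_data"))
  sbm_rts <- match.arg(sbm_rts)
  undesirable <- match.arg(undesirable)
  ds <- if (is.null(data$transformed)) {
    transform_undesirable(data, undesirable)
  } else {
    data
  }
  n <- nrow(ds$X)
  sols <- vector("list", n)
  te <- pte <- rho <- super_sbm <- numeric(n)
  rts_label <- character(n)
  for (o in seq_len(n)) {
    ccr <- solve_radial(ds, o, "crs", control)
    bcc <- solve_radial(ds, o, "vrs", control)
    dec <- decompose_efficiency(ccr, bcc)
    cls <- classify_rts(ds, o, control, theta = ccr$theta)
    sbm <- solve_sbm(ds, o, sbm_rts, control)
    sup <- if (super) solve_super_sbm(ds, o, sbm_rts, control, sbm = sbm)
           else sbm$rho
    te[o] <- dec[["te"]]; pte[o] <- dec[["pte"]]
    rho[o] <- sbm$rho; super_sbm[o] <- sup
    rts_label[o] <- cls$label
    sols[[o]] <- list(ccr = ccr, bcc = bcc, sbm = sbm, rts = cls)
  }
  names(sols) <- ds$dmu_ids
  results <- data.frame(dmu = ds$dmu_ids, te = te, pte = pte, se = te / pte,
                        rts = rts_label, sbm = rho, super_sbm = super_sbm,
                        row.names = NULL, stringsAsFactors = FALSE)
  results$rank <- rank_dmus(results$dmu, results$super_sbm)
  structure(list(results = results, solutions = sols, data = ds,
                 sbm_rts = sbm_rts, control = control),
            class = "dea")
}

#' @export
print.dea <- function(x, digits = 3, ...) {
  cat(sprintf("DEA efficiency analysis: %d DMUs, %d inputs, %d outputs\n",
              nrow(x$data$X), ncol(x$data$X), ncol(x$data$Y)))
  df <- x$results
  num <- vapply(df, is.numeric, TRUE) & names(df) != "rank"
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summary statistics of a DEA analysis
#'
#' Reports the headline figures of a first-stage run: mean TE, PTE, SE and
#' SBM efficiency, the number of fully efficient DMUs, and the
#' returns-to-scale counts.
#'
#' @param object a fitted [dea] object.
#' @param ... unused.
#' @return a list of class `"summary.dea"` (see [summarize_efficiency()]).
#' @export
summary.dea <- function(object, ...) {
  summarize_efficiency(object$results)
}

#' Summarise an efficiency table
#'
#' Works on the `results` data frame of a [dea] fit or any table in the same
#' layout (e.g. the packaged published table from [ltcf_table3()]): per-model
#' mean scores, count of efficient DMUs, and RTS counts.
#'
#' @param tab data frame with columns `te`, `pte`, `se`, `rts` and `sbm`.
#' @param efficiency_tol scores within this of 1 count as efficient.
#' @return a list of class `"summary.dea"` with elements `n`, `mean_te`,
#'   `mean_pte`, `mean_se`, `mean_sbm`, `n_efficient`, `rts_counts`.
#' @export
summarize_efficiency <- function(tab, efficiency_tol = 1e-6) {
  need <- c("te", "pte", "se", "rts", "sbm")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("malformed efficiency table; missing columns: ",
                         paste(miss, collapse = ", "))
  rts <- factor(tab$rts, levels = c("CRS", "IRS", "DRS"))
  if (anyNA(rts)) stop("malformed efficiency table: RTS labels must be ",
                       "CRS, IRS or DRS")
  structure(list(n = nrow(tab),
                 mean_te = mean(tab$te), mean_pte = mean(tab$pte),
                 mean_se = mean(tab$se), mean_sbm = mean(tab$sbm),
                 n_efficient = sum(tab$te >= 1 - efficiency_tol),
                 rts_counts = table(rts)),
            class = "summary.dea")
}

#' @export
print.summary.dea <- function(x, ...) {
  cat(sprintf("n = %d DMUs; efficient: %d (%.1f%%)\n", x$n, x$n_efficient,
              100 * x$n_efficient / x$n))
  cat(sprintf("mean TE %.3f | mean PTE %.3f | mean SE %.3f | mean SBM %.3f\n",
              x$mean_te, x$mean_pte, x$mean_se, x$mean_sbm))
  cat(sprintf("returns to scale: %d CRS, %d IRS, %d DRS\n",
              x$rts_counts[["CRS"]], x$rts_counts[["IRS"]],
              x$rts_counts[["DRS"]]))
  invisible(x)
}

#' Extract the per-DMU efficiency table
#'
#' @param x a fitted [dea] object.
#' @return the `results` data frame (one row per DMU).
#' @export
efficiency_table <- function(x) {
  stopifnot(inherits(x, "dea"))
  x$results
}

#' @export
plot.dea <- function(x, which = c("sbm", "te", "pte"), ...) {
  which <- match.arg(which)
  sc <- x$results[[which]]
  ord <- order(sc, decreasing = TRUE)
  graphics::barplot(sc[ord], names.arg = x$results$dmu[ord], las = 2,
                    ylim = c(0, 1.05), ylab = paste(toupper(which), "score"),
                    xlab = "DMU", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
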