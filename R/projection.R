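#' Frontier projection of one DMU
#'
#' Computes the frontier target the solved model prescribes for DMU `o`.
#' For an SBM solution the input target is `x_o - s-` and the output target
#' the reference combination `Y'lambda`; for a radial solution the input
#' target is `theta * x_o - s-` and the output target `y_o + s+`. The
#' projected point lies on the frontier: re-solving efficiency at the
#' projection yields a score of one.
#'
#' @param sol a `"dea_solution"` from [solve_sbm()] or [solve_radial()].
#' @param ds the [dmu_data] object the solution was computed on.
#' @param o DMU index or id; must match `sol$dmu`.
#' @return a list with numeric vectors `inputs` and `outputs` (the targets)
#'   and `actual_inputs`, `actual_outputs`.
#' @export
project_dmu <- function(sol, ds, o) {
  stopifnot(inherits(sol, "dea_solution"), inherits(ds, "dmu_data"))
  o <- .resolve_dmu(ds, o)
  if (!identical(sol$dmu, ds$dmu_ids[o])) {
    stop("solution is for DMU ", sol$dmu, ", not ", ds$dmu_ids[o])
  }
  x_o <- ds$X[o, ]; y_o <- ds$Y[o, ]
  if (sol$model == "sbm") {
    xin <- pmax(x_o - sol$input_slacks, 0)
    yout <- pmax(as.numeric(t(ds$Y) %*% sol$lambda), y_o)
  } else {
    xin <- pmax(sol$theta * x_o - sol$input_slacks, 0)
    yout <- y_o + sol$output_slacks
  }
  names(yout) <- colnames(ds$Y)
  list(inputs = xin, outputs = yout,
       actual_inputs = x_o, actual_outputs = y_o)
}

#' Per-indicator input adjustment table for a DMU subset
#'
#' For each DMU in `subset` and each input indicator, reports the actual
#' value, the frontier projection, the number of adjustments
#' `NA = actual - projection` (same units as the indicator) and the
#' adjustment proportion `NA / actual x 100` (percent), plus an arithmetic
#' mean row over the subset. This is the slack analysis conventionally run
#' on the DMUs under decreasing returns to scale, quantifying how much of
#' each input could be shed without reducing any output.
#'
#' @param fit a fitted [dea] object.
#' @param subset DMU ids or indices to tabulate; defaults to the DMUs
#'   classified DRS. Must be non-empty.
#' @param source which solution's slacks define the projection: `"sbm"`
#'   (default) or `"radial"` (the BCC phase-2 slacks).
#' @return a data frame of class `"projection_table"`: columns `dmu`,
#'   `indicator`, `actual`, `projection`, `na`, `pct`, long format, with a
#'   trailing `"Mean"` block averaging each indicator over the subset.
#' @export
adjustment_table <- function(fit, subset = NULL, source = c("sbm", "radial")) {
  stopifnot(inherits(fit, "dea"))
  source <- match.arg(source)
  ds <- fit$data
  if (is.null(subset)) subset <- fit$results$dmu[fit$results$rts == "DRS"]
  if (!length(subset)) stop("empty DMU subset")
  idx <- vapply(subset, function(o) .resolve_dmu(ds, o), 1L)
  rows <- lapply(idx, function(o) {
    sol <- if (source == "sbm") fit$solutions[[o]]$sbm
           else fit$solutions[[o]]$bcc
    pr <- project_dmu(sol, ds, o)
    amt <- pmax(pr$actual_inputs - pr$inputs, 0)
    data.frame(dmu = ds$dmu_ids[o], indicator = colnames(ds$X),
               actual = unname(pr$actual_inputs),
               projection = unname(pr$inputs),
               na = unname(amt),
               pct = unname(100 * amt / pr$actual_inputs),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  mean_block <- do.call(rbind, lapply(split(tab, tab$indicator)[
    unique(tab$indicator)], function(g) {
      data.frame(dmu = "Mean", indicator = g$indicator[1],
                 actual = mean(g$actual), projection = mean(g$projection),
                 na = mean(g$na), pct = mean(g$pct),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  out <- rbind(tab, mean_block)
  rownames(out) <- NULL
  class(out) <- c("projection_table", "data.frame")
  out
}

#' @export
print.projection_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df$actual <- round(df$actual, digits)
  df$projection <- round(df$projection, digits)
  df$na <- round(df$na, digits)
  df$pct <- sprintf("%.2f%%", df$pct)
  print(df, row.names = FALSE)
  invisible(x)
}
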