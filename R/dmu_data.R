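#' Construct a DMU dataset
#'
#' Bundles the input and output matrices of a set of decision-making units
#' (DMUs) — here, long-term care facilities — together with per-output
#' direction flags and optional second-stage covariates, and validates the
#' envelopment preconditions: every input strictly positive (the slacks-based
#' measure divides by inputs), every output non-negative, no missing cells.
#'
#' @param inputs numeric matrix or data frame, one row per DMU, one column per
#'   input indicator (e.g. fixed assets in million yuan, staff headcounts,
#'   beds). All cells must be finite and strictly positive.
#' @param outputs numeric matrix or data frame, one row per DMU, one column
#'   per output indicator (resident counts, quality rates in percent).
#'   All cells must be finite and non-negative.
#' @param dmu_ids character vector of DMU labels; defaults to row names or
#'   `"1".."n"`.
#' @param output_direction character vector, one of `"desirable"` or
#'   `"undesirable"` per output column. Undesirable outputs (fall rate,
#'   unhandled-complaint rate, major-accident incidence) are those where lower
#'   is better and must be transformed (see [transform_undesirable()]) before
#'   a DEA solve.
#' @param covariates optional data frame of per-DMU covariates for the
#'   second-stage Tobit regression; must have one row per DMU.
#'
#' @return an object of class `"dmu_data"`: a list with elements `dmu_ids`,
#'   `X` (n x m input matrix), `Y` (n x s output matrix), `output_direction`,
#'   `covariates`, and `transformed` (bookkeeping for undesirable-output
#'   transforms).
#' @seealso [read_dmu_data()], [check_adequacy()], [dea()]
#' @export
#' @examples
#' d <- dmu_data(inputs = cbind(x = c(1, 2)), outputs = cbind(y = c(1, 1)))
#' d
dmu_data <- function(inputs, outputs, dmu_ids = NULL,
                     output_direction = NULL, covariates = NULL) {
  X <- as.matrix(inputs)
  Y <- as.matrix(outputs)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  n <- nrow(X)
  if (n < 1L || ncol(X) < 1L || ncol(Y) < 1L) {
    stop("need at least one DMU, one input and one output")
  }
  if (nrow(Y) != n) stop("inputs and outputs disagree on the number of DMUs")
  if (is.null(dmu_ids)) {
    dmu_ids <- rownames(X)
    if (is.null(dmu_ids)) dmu_ids <- as.character(seq_len(n))
  }
  dmu_ids <- as.character(dmu_ids)
  if (length(dmu_ids) != n) stop("dmu_ids must have one label per DMU")
  if (anyDuplicated(dmu_ids)) stop("duplicate DMU ids: ",
                                   paste(unique(dmu_ids[duplicated(dmu_ids)]),
                                         collapse = ", "))
  if (is.null(colnames(X))) colnames(X) <- paste0("input_", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("output_", seq_len(ncol(Y)))
  .check_cells(X, dmu_ids, positive = TRUE, what = "input")
  .check_cells(Y, dmu_ids, positive = FALSE, what = "output")
  if (is.null(output_direction)) {
    output_direction <- rep("desirable", ncol(Y))
  }
  output_direction <- match.arg(output_direction,
                                c("desirable", "undesirable"),
                                several.ok = TRUE)
  if (length(output_direction) == 1L) {
    output_direction <- rep(output_direction, ncol(Y))
  }
  if (length(output_direction) != ncol(Y)) {
    stop("output_direction must flag every output column")
  }
  names(output_direction) <- colnames(Y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per DMU")
  }
  rownames(X) <- rownames(Y) <- dmu_ids
  structure(list(dmu_ids = dmu_ids, X = X, Y = Y,
                 output_direction = output_direction,
                 covariates = covariates,
                 transformed = NULL),
            class = "dmu_data")
}

.check_cells <- function(M, ids, positive, what) {
  bad <- which(!is.finite(M) | (if (positive) M <= 0 else M < 0),
               arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "%s '%s' of DMU '%s' is %s (got %s); %ss must be %s",
      what, colnames(M)[j], ids[i],
      if (is.finite(M[i, j])) "out of range" else "missing or non-numeric",
      format(M[i, j]), what,
      if (positive) "strictly positive" else "non-negative"))
  }
  invisible(TRUE)
}

#' @export
print.dmu_data <- function(x, ...) {
  cat(sprintf("DMU dataset: %d units, %d inputs, %d outputs\n",
              nrow(x$X), ncol(x$X), ncol(x$Y)))
  und <- names(x$output_direction)[x$output_direction == "undesirable"]
  if (length(und)) cat("undesirable outputs:", paste(und, collapse = ", "), "\n")
  if (!is.null(x$transformed)) cat("undesirable outputs transformed:",
                                   x$transformed$method, "\n")
  if (!is.null(x$covariates)) {
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.dmu_data <- function(x) c(nrow(x$X), ncol(x$X), ncol(x$Y))

#' Read a DMU dataset from CSV
#'
#' Reads a comma-separated, UTF-8, header-required facility table (one row
#' per DMU) and maps its columns to inputs, outputs and covariates through a
#' schema. Percentages are kept on the 0-100 scale as stored.
#'
#' @param path path to the CSV file.
#' @param schema a list with character vectors `inputs` and `outputs`
#'   (column names, in the order the matrices should take), and optionally
#'   `id` (DMU label column), `undesirable` (subset of `outputs` where lower
#'   is better) and `covariates`.
#' @return a validated [dmu_data] object; X/Y column order follows the schema.
#' @export
read_dmu_data <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("no data rows in ", path)
  if (is.null(schema$inputs) || is.null(schema$outputs)) {
    stop("schema must name input and output columns")
  }
  want <- unique(c(schema$id, schema$inputs, schema$outputs, schema$covariates))
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  dup <- names(df)[duplicated(names(df)) & names(df) %in% want]
  if (length(dup)) stop("duplicate columns: ", paste(unique(dup), collapse = ", "))
  for (cl in c(schema$inputs, schema$outputs)) {
    if (!is.numeric(df[[cl]])) {
      stop("column '", cl, "' is not numeric")
    }
  }
  ids <- if (!is.null(schema$id)) as.character(df[[schema$id]]) else NULL
  direction <- rep("desirable", length(schema$outputs))
  names(direction) <- schema$outputs
  if (!is.null(schema$undesirable)) {
    unknown <- setdiff(schema$undesirable, schema$outputs)
    if (length(unknown)) stop("undesirable flags name non-output columns: ",
                              paste(unknown, collapse = ", "))
    direction[schema$undesirable] <- "undesirable"
  }
  covs <- if (!is.null(schema$covariates)) df[schema$covariates] else NULL
  dmu_data(inputs = df[schema$inputs], outputs = df[schema$outputs],
           dmu_ids = ids, output_direction = unname(direction),
           covariates = covs)
}

#' Write a DMU dataset to CSV
#'
#' Inverse of [read_dmu_data()]: writes id, input, output and covariate
#' columns in schema order, full precision (round-trips finite decimals
#' bit-exactly).
#'
#' @param ds a [dmu_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dmu_data <- function(ds, path) {
  stopifnot(inherits(ds, "dmu_data"))
  df <- data.frame(dmu = ds$dmu_ids, ds$X, ds$Y, check.names = FALSE)
  if (!is.null(ds$covariates)) df <- cbind(df, ds$covariates)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Sample-size and correlation screening for a DMU dataset
#'
#' Applies the rule of thumb that the number of DMUs should be at least twice
#' the number of input plus output indicators, and reports the input-output
#' Pearson correlation matrix as a screening diagnostic (reported, not
#' enforced). Columns with zero variance get `NA` correlations.
#'
#' @param ds a [dmu_data] object.
#' @return a list of class `"dmu_adequacy"`: `n`, `m`, `s`, `threshold`
#'   (`2 * (m + s)`), `adequate` (logical), and `correlation` (m x s matrix of
#'   input-output Pearson correlations).
#' @export
check_adequacy <- function(ds) {
  stopifnot(inherits(ds, "dmu_data"))
  n <- nrow(ds$X); m <- ncol(ds$X); s <- ncol(ds$Y)
  corr <- matrix(NA_real_, m, s, dimnames = list(colnames(ds$X), colnames(ds$Y)))
  for (i in seq_len(m)) {
    for (j in seq_len(s)) {
      if (n > 1 && stats::sd(ds$X[, i]) > 0 && stats::sd(ds$Y[, j]) > 0) {
        corr[i, j] <- stats::cor(ds$X[, i], ds$Y[, j])
      }
    }
  }
  structure(list(n = n, m = m, s = s, threshold = 2L * (m + s),
                 adequate = n >= 2 * (m + s), correlation = corr),
            class = "dmu_adequacy")
}

#' @export
print.dmu_adequacy <- function(x, ...) {
  cat(sprintf("DMU adequacy: n = %d vs 2(m+s) = %d -> %s\n", x$n, x$threshold,
              if (x$adequate) "adequate" else "inadequate"))
  cat("input-output Pearson correlations:\n")
  print(round(x$correlation, 3))
  invisible(x)
}
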