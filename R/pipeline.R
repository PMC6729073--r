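#' Read a pipeline run configuration
#'
#' Reads a plain-text YAML configuration for [run_pipeline()]. Known keys:
#' `dataset` (CSV path), `covariates` (optional CSV path), `out_dir`,
#' `schema` (column mapping, see [read_dmu_data()]), `sbm_rts`,
#' `undesirable`, `super`, `tobit` (logical), `tobit_score` (`bcc`/`sbm`),
#' `censor_lower`, `censor_upper`, `projection_source` (`sbm`/`radial`),
#' `seed`, `verbose`. Unknown keys are rejected.
#'
#' @param path path to the YAML file.
#' @return a named list of class `"run_config"` with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(dataset = NULL, covariates = NULL, out_dir = ".",
                   schema = NULL, sbm_rts = "vrs", undesirable = "translate",
                   super = TRUE, tobit = FALSE, tobit_score = "bcc",
                   censor_lower = 0, censor_upper = 1,
                   projection_source = "sbm", seed = 1L, verbose = TRUE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(defaults, cfg)
  if (is.null(out$dataset)) stop("config must set 'dataset'")
  structure(out, class = "run_config")
}

#' Run the full two-stage efficiency pipeline
#'
#' Executes validate -> radial CCR/BCC -> decomposition and RTS -> SBM ->
#' super-SBM ranking -> input projections for the DRS subset -> (optionally)
#' the second-stage Tobit regression, and writes the result tables to
#' `out_dir`: `efficiency.csv` (per-DMU TE/PTE/SE/RTS/SBM/rank, both at
#' display rounding and full precision in `efficiency_raw.csv`),
#' `projections.csv`, `tobit.csv` + `tobit.json` (when run), a `summary.json`
#' block and a `run_log.txt` recording the seed, tolerances and package
#' version. With a fixed seed the numeric outputs are byte-identical across
#' runs.
#'
#' @param config a `"run_config"` list from [read_run_config()], or a path
#'   to a YAML config file.
#' @param data optional [dmu_data] object overriding `config$dataset`
#'   (useful when driving the pipeline from R).
#' @return invisibly, a list with the fitted `dea` object, the projection
#'   table, the Tobit fit (or `NULL`) and the summary; called for its
#'   side-effect of writing `out_dir`.
#' @export
run_pipeline <- function(config, data = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stage <- "configuration"
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  tryCatch({
    stage <- "validate"
    ds <- if (!is.null(data)) data else {
      schema <- config$schema
      if (is.null(schema)) stop("config must set 'schema' to read a dataset")
      read_dmu_data(config$dataset, schema)
    }
    adequacy <- check_adequacy(ds)
    if (!adequacy$adequate) {
      say(sprintf("note: n = %d below the 2(m+s) = %d rule of thumb",
                  adequacy$n, adequacy$threshold))
    }
    if (isTRUE(config$tobit) && is.null(ds$covariates)) {
      stop("second stage requires covariates")
    }
    set.seed(as.integer(config$seed))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "dea"
    fit <- dea(ds, sbm_rts = config$sbm_rts, undesirable = config$undesirable,
               super = isTRUE(config$super))
    res <- fit$results
    raw_path <- file.path(config$out_dir, "efficiency_raw.csv")
    utils::write.csv(res, raw_path, row.names = FALSE)
    disp <- res
    for (cl in c("te", "pte", "se", "sbm", "super_sbm")) {
      disp[[cl]] <- round(disp[[cl]], 3)
    }
    utils::write.csv(disp, file.path(config$out_dir, "efficiency.csv"),
                     row.names = FALSE)

    stage <- "projection"
    drs <- res$dmu[res$rts == "DRS"]
    proj <- if (length(drs)) {
      adjustment_table(fit, drs, source = config$projection_source)
    } else {
      empty <- data.frame(dmu = character(), indicator = character(),
                          actual = numeric(), projection = numeric(),
                          na = numeric(), pct = numeric())
      class(empty) <- c("projection_table", "data.frame")
      empty
    }
    pdisp <- as.data.frame(proj)
    pdisp$pct <- round(pdisp$pct, 2)
    utils::write.csv(pdisp, file.path(config$out_dir, "projections.csv"),
                     row.names = FALSE)

    tfit <- NULL
    if (isTRUE(config$tobit)) {
      stage <- "tobit"
      cov_tab <- cbind(dmu = ds$dmu_ids, ds$covariates)
      tfit <- run_second_stage(res, cov_tab, which_score = config$tobit_score,
                               lower = config$censor_lower,
                               upper = config$censor_upper)
      ts <- summary(tfit)
      ttab <- cbind(term = rownames(ts$table), ts$table)
      ttab[-1] <- lapply(ttab[-1], round, 3)
      utils::write.csv(ttab, file.path(config$out_dir, "tobit.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(coefficients = as.list(round(tfit$coefficients, 6)),
             sigma = tfit$sigma, loglik = tfit$loglik,
             loglik_null = tfit$loglik_null, pseudo_r2 = ts$pseudo_r2,
             lr = ts$lr, lr_p = ts$lr_p),
        file.path(config$out_dir, "tobit.json"),
        auto_unbox = TRUE, digits = NA)
    }

    stage <- "summary"
    sm <- summarize_efficiency(res)
    jsonlite::write_json(
      list(n = sm$n, mean_te = sm$mean_te, mean_pte = sm$mean_pte,
           mean_se = sm$mean_se, mean_sbm = sm$mean_sbm,
           n_efficient = sm$n_efficient,
           rts_counts = as.list(as.integer(sm$rts_counts)) |>
             stats::setNames(names(sm$rts_counts))),
      file.path(config$out_dir, "summary.json"), auto_unbox = TRUE,
      digits = NA)
    ctrl <- fit$control
    writeLines(c(
      sprintf("ltcfdea %s", as.character(utils::packageVersion("ltcfdea"))),
      sprintf("seed: %d", as.integer(config$seed)),
      sprintf("lp tolerance: %g; efficiency tolerance: %g",
              ctrl$tolerance, ctrl$efficiency_tol),
      sprintf("sbm rts: %s; undesirable treatment: %s; projections: %s",
              config$sbm_rts, config$undesirable, config$projection_source),
      sprintf("dmus: %d; inputs: %d; outputs: %d", adequacy$n, adequacy$m,
              adequacy$s),
      sprintf("adequacy: n %s 2(m+s) = %d", if (adequacy$adequate) ">=" else "<",
              adequacy$threshold)),
      file.path(config$out_dir, "run_log.txt"))
    say("pipeline complete: ", config$out_dir)
    invisible(list(dea = fit, projections = proj, tobit = tfit, summary = sm))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
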