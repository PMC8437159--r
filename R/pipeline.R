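#' Pipeline configuration
#'
#' Exactly one of `input` (path to a survey CSV) or `synthetic` (a
#' [synthetic_config()], or `TRUE` for the default one) must be given. All
#' randomness flows from `seed`: when simulating, the synthetic config's own
#' seed is overridden by a sub-stream derived from the pipeline seed, so one
#' (config, seed) pair pins the whole bundle.
#'
#' @param input path to an existing survey CSV, or `NULL`.
#' @param synthetic a [synthetic_config()], `TRUE`, or `NULL`.
#' @param codebook path to a codebook JSON (default: the packaged one).
#' @param scoring a [scoring_options()].
#' @param outcomes score outcomes to model (`"dds"`, `"pdqs"`).
#' @param scopes model scopes (`"combined"`, `"per_country"`).
#' @param alpha univariate screening threshold.
#' @param cluster cluster column for the GEE.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed recorded in the manifest.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `dietshock_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, codebook = NULL,
                            scoring = scoring_options(),
                            outcomes = c("dds", "pdqs"),
                            scopes = "combined", alpha = 0.20,
                            cluster = "site", out_dir = "dietshock_out",
                            seed = 1L, log_level = c("info", "quiet")) {
  cfg <- structure(list(input = input, synthetic = synthetic,
                        codebook = codebook, scoring = scoring,
                        outcomes = outcomes, scopes = scopes, alpha = alpha,
                        cluster = cluster, out_dir = out_dir,
                        seed = as.integer(seed),
                        log_level = match.arg(log_level)),
                   class = "dietshock_pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg a pipeline config.
#' @export
validate_pipeline_config <- function(cfg) {
  fail <- function(msg) abort(msg, "dietshock_config_error")
  has_input <- !is.null(cfg$input)
  has_syn <- !is.null(cfg$synthetic) && !identical(cfg$synthetic, FALSE)
  if (has_input == has_syn)
    fail("exactly one of 'input' and 'synthetic' must be configured")
  if (!length(cfg$outcomes) || !all(cfg$outcomes %in% c("dds", "pdqs")))
    fail("outcomes must be a subset of dds, pdqs")
  if (!all(cfg$scopes %in% c("combined", "per_country")))
    fail("scopes must be a subset of combined, per_country")
  if (is.na(cfg$seed)) fail("seed must be an integer")
  invisible(cfg)
}

#' Read a pipeline configuration from JSON
#'
#' Recognized keys: `input`, `synthetic` (`true` or an object of
#' [synthetic_config()] overrides: `n_per_site`, `site_sd`, `overdispersion`,
#' `during_drift`, `missingness`, `effects`, `baseline_logit`), `codebook`,
#' `scoring` (`dds_days_threshold`, `aggregator`, `completeness_threshold`),
#' `outcomes`, `scopes`, `alpha`, `cluster`, `out_dir`, `seed`, `log_level`.
#'
#' @param path JSON file path.
#' @return a validated `dietshock_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    abort(paste0("config file not found: ", path), "dietshock_io_error")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- raw$synthetic
  if (!is.null(syn) && !isTRUE(syn) && !identical(syn, FALSE)) {
    args <- list()
    for (f in c("site_sd", "overdispersion", "during_drift", "seed"))
      if (!is.null(syn[[f]])) args[[f]] <- syn[[f]]
    for (f in c("n_per_site", "missingness", "baseline_logit"))
      if (!is.null(syn[[f]])) args[[f]] <- unlist(syn[[f]])
    if (!is.null(syn$effects)) args$effects <- lapply(syn$effects, unlist)
    syn <- do.call(synthetic_config, args)
  }
  scoring <- if (is.null(raw$scoring)) scoring_options()
  else do.call(scoring_options, raw$scoring)
  pipeline_config(
    input = raw$input, synthetic = syn, codebook = raw$codebook,
    scoring = scoring,
    outcomes = raw$outcomes %||% c("dds", "pdqs"),
    scopes = raw$scopes %||% "combined",
    alpha = raw$alpha %||% 0.20, cluster = raw$cluster %||% "site",
    out_dir = raw$out_dir %||% "dietshock_out", seed = raw$seed %||% 1L,
    log_level = raw$log_level %||% "info")
}

# internal: deterministic CSV writer (no row names, NA as empty string)
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  path
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, score, describe, model and report stages,
#' writing a reproducible bundle to `cfg$out_dir`: `survey_scored.csv`,
#' descriptive tables, tidy model results plus a formatted text report, a
#' run log, and `manifest.json` (config + seed + versions). Identical config
#' and seed give a byte-identical bundle. A stage failure leaves partial
#' outputs plus a `FAILED` marker naming the stage, and re-raises.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list with `records` (scored), `descriptives`, `models`,
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (cfg$log_level == "info") message(line)
  }
  stage <- "init"
  on_fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n",
                      conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)), "dietshock_pipeline_error")
  }
  tryCatch({
    cb <- if (is.null(cfg$codebook)) default_codebook()
          else read_codebook(cfg$codebook)

    stage <- "ingest"
    if (!is.null(cfg$input)) {
      say("ingest: reading ", cfg$input)
      records <- read_survey_table(cfg$input, cb)
      truth <- NULL
    } else {
      syn <- if (isTRUE(cfg$synthetic)) synthetic_config() else cfg$synthetic
      syn$seed <- derive_seed(cfg$seed, "synthetic")
      say("ingest: simulating ", sum(syn$n_per_site), " households")
      gen <- generate_survey(syn)
      records <- gen$records
      truth <- gen$truth
      write_table_csv(records, file.path(cfg$out_dir, "survey_raw.csv"))
      jsonlite::write_json(
        list(site_effects = as.list(truth$site_effects),
             during_drift = truth$during_drift, effects = truth$effects),
        file.path(cfg$out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }

    stage <- "score"
    records <- score_survey(records, cb, cfg$scoring)
    n_incomplete <- sum(!records$complete_before | !records$complete_during,
                        na.rm = TRUE)
    say("score: ", nrow(records), " households scored; ", n_incomplete,
        " with incomplete recall excluded from score analyses")
    write_table_csv(records, file.path(cfg$out_dir, "survey_scored.csv"))

    stage <- "describe"
    chars <- characteristics_table(records)
    prices <- price_change_table(records)
    chg_m <- consumption_change_summary(records, "mddw", cb, cfg$scoring)
    chg_p <- consumption_change_summary(records, "pdqs", cb, cfg$scoring)
    scores <- mean_scores_before_during(records)
    write_table_csv(chars$frequencies,
                    file.path(cfg$out_dir, "characteristics.csv"))
    write_table_csv(chars$continuous,
                    file.path(cfg$out_dir, "characteristics_continuous.csv"))
    write_table_csv(prices, file.path(cfg$out_dir, "price_food_security.csv"))
    write_table_csv(chg_m, file.path(cfg$out_dir, "change_summary_mddw.csv"))
    write_table_csv(chg_p, file.path(cfg$out_dir, "change_summary_pdqs.csv"))
    write_table_csv(scores, file.path(cfg$out_dir, "score_summary.csv"))
    say("describe: tables written")

    stage <- "model"
    model_rows <- list()
    reports <- list()
    models <- list()
    for (oc in cfg$outcomes) for (sc in cfg$scopes) {
      say("model: outcome=", oc, " scope=", sc)
      res <- build_and_fit(records, model_spec(
        outcome = oc, scope = sc, alpha = cfg$alpha, cluster = cfg$cluster))
      models[[paste(oc, sc, sep = "_")]] <- res
      model_rows[[paste(oc, sc)]] <- res$results
      reports[[paste(oc, sc)]] <- results_report(res)
    }
    results <- do.call(rbind, model_rows)
    rownames(results) <- NULL
    write_table_csv(results, file.path(cfg$out_dir, "model_results.csv"))

    stage <- "report"
    rep_txt <- character(0)
    for (nm in names(reports)) {
      rep_txt <- c(rep_txt, paste0("== ", nm, " =="), "")
      rep_txt <- c(rep_txt, utils::capture.output(print(reports[[nm]],
                                                        row.names = FALSE)),
                   "")
    }
    writeLines(rep_txt, file.path(cfg$out_dir, "model_report.txt"))
    manifest <- list(
      package = "dietshock",
      package_version = as.character(utils::packageVersion("dietshock")),
      r_version = R.version.string,
      seed = cfg$seed,
      outcomes = cfg$outcomes, scopes = cfg$scopes, alpha = cfg$alpha,
      cluster = cfg$cluster,
      input = cfg$input %||% "synthetic",
      n_records = nrow(records),
      outputs = sort(setdiff(list.files(cfg$out_dir),
                             c("manifest.json", "run.log", "FAILED"))))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log_lines, log_path)
    if (file.exists(file.path(cfg$out_dir, "FAILED")))
      unlink(file.path(cfg$out_dir, "FAILED"))
    say("done: bundle in ", cfg$out_dir)
    invisible(list(records = records,
                   descriptives = list(characteristics = chars,
                                       prices = prices,
                                       change_mddw = chg_m,
                                       change_pdqs = chg_p,
                                       scores = scores),
                   models = models, out_dir = cfg$out_dir))
  }, error = function(e) {
    if (inherits(e, "dietshock_pipeline_error")) stop(e)
    on_fail(e)
  })
}

cli_usage <- function() {
  paste(
    "usage: dietshock <command> [options]",
    "",
    "commands:",
    "  simulate   --config <json> [--seed <int>] --out <dir>",
    "  score      --in <survey.csv> --out <scored.csv>",
    "  describe   --in <scored.csv> --out <dir>",
    "  model      --in <scored.csv> --out <dir> [--outcome dds|pdqs]",
    "             [--scope combined|per_country]",
    "  run-all    --config <json> [--seed <int>] [--out <dir>]",
    "",
    "options: --config --seed --out --in --log-level --version",
    sep = "\n")
}

# internal: parse "--flag value" pairs after the subcommand
parse_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      abort(paste0("unexpected argument: ", a), "dietshock_cli_error")
    if (i == length(argv))
      abort(paste0("flag ", a, " needs a value"), "dietshock_cli_error")
    flags[[substring(a, 3)]] <- argv[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `score`, `describe`, `model`, `run-all`.
#' Returns the process exit code invisibly (0 success, 2 usage error) so it
#' can be called in-process; the installed `exec/dietshock` script forwards
#' the code to `quit()`.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return integer exit code, invisibly.
#' @export
dietshock_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message(cli_usage())
    return(invisible(2L))
  }
  if (argv[1] %in% c("--version", "-V")) {
    cat("dietshock", as.character(utils::packageVersion("dietshock")), "\n")
    return(invisible(0L))
  }
  cmd <- argv[1]
  if (!cmd %in% c("simulate", "score", "describe", "model", "run-all")) {
    message("unknown subcommand: ", cmd, "\n", cli_usage())
    return(invisible(2L))
  }
  res <- tryCatch({
    flags <- parse_flags(argv[-1])
    quiet <- identical(flags[["log-level"]], "quiet")
    if (cmd == "simulate") {
      cfg <- if (!is.null(flags$config)) read_pipeline_config(flags$config)
             else pipeline_config(synthetic = TRUE)
      if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
      syn <- if (isTRUE(cfg$synthetic) || is.null(cfg$synthetic))
        synthetic_config() else cfg$synthetic
      syn$seed <- derive_seed(cfg$seed, "synthetic")
      out <- flags$out %||% "survey.csv"
      gen <- generate_survey(syn)
      write_survey_table(gen$records, out)
      if (!quiet) message("wrote ", out, " (", nrow(gen$records),
                          " households)")
    } else if (cmd == "score") {
      if (is.null(flags[["in"]]) || is.null(flags$out))
        abort("score needs --in and --out", "dietshock_cli_error")
      rec <- read_survey_table(flags[["in"]])
      rec <- score_survey(rec)
      write_table_csv(rec, flags$out)
      if (!quiet) message("wrote ", flags$out)
    } else if (cmd == "describe") {
      if (is.null(flags[["in"]]) || is.null(flags$out))
        abort("describe needs --in and --out", "dietshock_cli_error")
      rec <- read_survey_table_scored(flags[["in"]])
      dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
      write_table_csv(characteristics_table(rec)$frequencies,
                      file.path(flags$out, "characteristics.csv"))
      write_table_csv(price_change_table(rec),
                      file.path(flags$out, "price_food_security.csv"))
      write_table_csv(consumption_change_summary(rec, "mddw"),
                      file.path(flags$out, "change_summary_mddw.csv"))
      write_table_csv(consumption_change_summary(rec, "pdqs"),
                      file.path(flags$out, "change_summary_pdqs.csv"))
      write_table_csv(mean_scores_before_during(rec),
                      file.path(flags$out, "score_summary.csv"))
      if (!quiet) message("wrote tables to ", flags$out)
    } else if (cmd == "model") {
      if (is.null(flags[["in"]]) || is.null(flags$out))
        abort("model needs --in and --out", "dietshock_cli_error")
      rec <- read_survey_table_scored(flags[["in"]])
      res <- build_and_fit(rec, model_spec(
        outcome = flags$outcome %||% "dds",
        scope = flags$scope %||% "combined"))
      dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
      write_table_csv(res$results, file.path(flags$out, "model_results.csv"))
      writeLines(utils::capture.output(print(results_report(res),
                                             row.names = FALSE)),
                 file.path(flags$out, "model_report.txt"))
      if (!quiet) message("wrote model results to ", flags$out)
    } else {  # run-all
      cfg <- if (!is.null(flags$config)) read_pipeline_config(flags$config)
             else pipeline_config(synthetic = TRUE)
      if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
      if (!is.null(flags$out)) cfg$out_dir <- flags$out
      if (quiet) cfg$log_level <- "quiet"
      run_pipeline(cfg)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (inherits(e, "dietshock_cli_error")) 2L else 1L
  })
  invisible(res)
}

# internal: read a scored survey CSV (schema columns + score columns)
read_survey_table_scored <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "dietshock_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  score_cols <- c("dds_before", "dds_during", "pdqs_before", "pdqs_during",
                  "complete_before", "complete_during")
  if (!all(score_cols %in% names(raw))) {
    rec <- read_survey_table(path)
    return(score_survey(rec))
  }
  raw
}
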