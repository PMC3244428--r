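# Configuration-driven runs and deterministic serialization.

config_error <- function(field, msg) {
  abort(sprintf("Config field `%s`: %s", field, msg), class = "config_error")
}

parse_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' does not exist.", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$seed)) config_error("seed", "required (no silent nondeterminism).")
  cfg$command <- cfg$command %||% "evaluate"
  if (!cfg$command %in% c("simulate", "test", "evaluate", "sweep")) {
    config_error("command", "must be simulate, test, evaluate or sweep.")
  }
  sc <- cfg$scenario %||% list()
  if (!is.null(sc$r)) {
    if (!is.numeric(sc$r) || sc$r < 0 || sc$r > 1) {
      config_error("r", sprintf("must be in [0, 1] (got %s).", sc$r))
    }
  }
  d <- sc$disease %||% list()
  disease <- tryCatch(
    disease_model(
      maf = d$maf %||% 0.3, prevalence = d$K %||% d$prevalence %||% 0.1,
      rr = d$rr %||% d$rr1 %||% 1, mode = d$mode %||% "additive",
      F = d$F %||% 0,
      maf_by_pop = unlist(d$maf_by_pop),
      prevalence_by_pop = unlist(d$prevalence_by_pop)),
    error = function(e) config_error("disease", conditionMessage(e)))
  scenario <- tryCatch(
    scenario_config(
      scenario = sc$scenario %||% 1, n_snps = sc$n_snps %||% 5500,
      maf_range = unlist(sc$maf_range) %||% c(0.05, 0.5),
      n_founders = sc$n_founders %||% 200,
      cases = unlist(sc$counts$cases), controls = unlist(sc$counts$controls),
      r = sc$r, disease = disease,
      fst = unlist(sc$fst),
      admix_within = sc$admix_within %||% TRUE),
    error = function(e) {
      if (inherits(e, "config_error")) stop(e)
      config_error("scenario", conditionMessage(e))
    })
  ev <- cfg$evaluation %||% list()
  eval <- tryCatch(
    eval_config(
      alpha = ev$alpha %||% 0.05, B = ev$B %||% 2000,
      rr_grid = unlist(ev$rr_grid) %||% c(1, 1.5, 2, 2.5),
      methods = unlist(ev$methods) %||%
        c("trend", "gc", "eigenstrat", "reg_pcs", "reg_real", "reg_est",
          "meta_fisher"),
      k_pcs = ev$k_pcs %||% 5, gc_estimator = ev$gc_estimator %||% "median",
      seed = cfg$seed),
    error = function(e) config_error("evaluation", conditionMessage(e)))
  list(command = cfg$command, scenario = scenario, eval = eval,
       sweep = cfg$sweep, out_dir = cfg$out_dir %||% ".", raw = cfg)
}

#' Write a results table in the fixed TSV dialect
#'
#' Fixed column order, floats at 6 significant digits, LF line endings:
#' byte-identical output for identical results across platforms.
#'
#' @param results A results tibble (any `strat_mc`-style table).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt6)
  con <- file(path, open = "wb")
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(df, sep = "\t")), con, sep = "\n")
  close(con)
  invisible(path)
}

#' Execute a run described by a config file
#'
#' Reads a YAML or JSON run configuration, executes the requested stage and
#' writes its outputs plus a JSON echo of the full configuration (enough to
#' reproduce the run) and a plain-text log.
#'
#' Commands: `simulate` (write one cohort as TSV), `test` (one cohort, all
#' configured association tests), `evaluate` (Monte-Carlo false positive
#' rate / power over the configured rr grid), `sweep` (`type: r`, `k`, or
#' `maf`).
#'
#' Schema (YAML keys): `command`, `seed` (required), `out_dir`,
#' `scenario: {scenario, n_snps, maf_range, n_founders, counts: {cases,
#' controls}, r, fst, admix_within, disease: {maf, K, rr, mode, F,
#' maf_by_pop, prevalence_by_pop}}`, `evaluation: {alpha, B, rr_grid,
#' methods, k_pcs, gc_estimator}`, `sweep: {type, grid}`.
#'
#' @param path Config file path.
#' @param quiet Suppress progress messages.
#' @return Named character vector of the files written, invisibly.
#' @export
run_from_config <- function(path, quiet = FALSE) {
  rc <- parse_run_config(path)
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("stratsim run: command=%s seed=%d", rc$command,
                         rc$eval$seed),
                 sprintf("scenario %d, %d null SNPs", rc$scenario$scenario,
                         rc$scenario$n_snps))
  say <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (!quiet) inform(msg)
  }
  files <- c()
  out <- function(name) file.path(rc$out_dir, name)

  if (rc$command == "simulate") {
    cohort <- build_cohort(rc$scenario, seed = rc$eval$seed)
    files <- export_cohort(cohort, out("cohort"))
    say(sprintf("Simulated cohort: %d individuals, %d null SNPs.",
                length(cohort$phenotype), ncol(cohort$genotypes)))
  } else if (rc$command == "test") {
    cohort <- build_cohort(rc$scenario, seed = rc$eval$seed)
    res <- run_association_tests(cohort, methods = rc$eval$methods,
                                 k_pcs = rc$eval$k_pcs,
                                 gc_estimator = rc$eval$gc_estimator)
    files <- c(results = write_results_tsv(res, out("tests.tsv")))
    say(sprintf("Ran %d association tests on one cohort.", nrow(res)))
  } else if (rc$command == "evaluate") {
    res <- power_curve(rc$scenario, rc$eval)
    files <- c(results = write_results_tsv(res, out("evaluation.tsv")))
    say(sprintf("Monte-Carlo evaluation: %d methods x %d relative risks, B = %d.",
                length(rc$eval$methods), length(rc$eval$rr_grid), rc$eval$B))
  } else if (rc$command == "sweep") {
    sw <- rc$sweep %||% list()
    type <- sw$type %||% config_error("sweep.type", "required for command sweep.")
    res <- switch(type,
      r = sweep_case_ratio(rc$scenario,
                           r_grid = unlist(sw$grid) %||% c(0, 0.25, 0.5, 0.75, 1),
                           eval = rc$eval, rr_power = sw$rr_power %||% 2),
      k = sweep_num_components(rc$scenario,
                               k_grid = unlist(sw$grid) %||% c(1, 2, 5, 10, 20, 50),
                               eval = rc$eval, rr_power = sw$rr_power %||% 2),
      maf = low_maf_eval(rc$scenario, eval = rc$eval,
                         low_maf = sw$low_maf %||% 0.01,
                         rr_power = sw$rr_power %||% 2),
      config_error("sweep.type", "must be r, k or maf."))
    files <- c(results = write_results_tsv(res, out(paste0("sweep_", type, ".tsv"))))
    say(sprintf("Sweep '%s' finished (%d rows).", type, nrow(res)))
  }

  echo <- list(config = rc$raw,
               package_version = as.character(utils::packageVersion("stratsim")),
               files = as.list(files))
  jsonlite::write_json(echo, out("run.json"), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  writeLines(log_lines, out("run.log"), sep = "\n")
  files <- c(files, json = out("run.json"), log = out("run.log"))
  invisible(files)
}
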