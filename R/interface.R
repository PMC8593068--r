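# I/O and workflow: the flat trial-data CSV, the JSON study configuration,
# a plain-text report, and the command-line driver (simulate / analyze /
# report). Data volumes are tiny (<= 840 clinicians x 3 rounds), so plain
# CSV keeps every artifact auditable.

TRIAL_CSV_COLS <- c("trial_id", "condition", "arm", "clinician_id", "round",
                    "estimate", "recommendation", "network_position",
                    "completed")

#' Write response records to the trial-data CSV
#'
#' Fixed header, UTF-8, empty field for a missing network position
#' (control condition). Round-trips losslessly through
#' [read_trial_csv()].
#'
#' @param records response-record data frame.
#' @param path output path.
#' @export
write_trial_csv <- function(records, path) {
  out <- records[TRIAL_CSV_COLS]
  out$estimate <- formatC(out$estimate, format = "g", digits = 15)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a trial-data CSV
#'
#' Checks the exact header and validates every row (estimate in
#' `[0, 100]`, known condition/arm/option codes, round in 1-3, network
#' position present iff network condition, no duplicate clinician-round
#' pairs), reporting offending line numbers.
#'
#' @param path CSV path.
#' @return A validated response-record data frame.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!identical(header, paste(TRIAL_CSV_COLS, collapse = ",")))
    stop("unexpected header in ", path, "; expected: ",
         paste(TRIAL_CSV_COLS, collapse = ","), call. = FALSE)
  rec <- utils::read.csv(
    path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
    colClasses = c(trial_id = "integer", condition = "character",
                   arm = "character", clinician_id = "character",
                   round = "integer", estimate = "numeric",
                   recommendation = "character",
                   network_position = "integer", completed = "integer"))
  if (nrow(rec) == 0L) return(rec)
  line <- seq_len(nrow(rec)) + 1L  # CSV line numbers (header is line 1)
  fail <- function(bad, what) {
    if (any(bad))
      stop("invalid ", what, " at line(s) ",
           paste(utils::head(line[bad], 5L), collapse = ", "),
           " of ", path, call. = FALSE)
  }
  fail(is.na(rec$trial_id) | rec$trial_id < 1L, "trial_id")
  fail(!rec$condition %in% CONDITION_LEVELS, "condition")
  fail(!rec$arm %in% ARM_LEVELS, "arm")
  fail(is.na(rec$round) | !rec$round %in% 1:3, "round")
  fail(is.na(rec$estimate) | rec$estimate < 0 | rec$estimate > 100,
       "estimate (must be in [0, 100])")
  fail(!rec$recommendation %in% OPTION_LEVELS, "recommendation")
  fail(is.na(rec$network_position) != (rec$condition == "control"),
       "network_position (required iff network condition)")
  fail(!rec$completed %in% c(0L, 1L), "completed flag")
  dup <- duplicated(rec[c("clinician_id", "round")])
  fail(dup, "duplicate clinician-round row")
  rec
}

# ---- study configuration --------------------------------------------------

#' Default study configuration
#'
#' The JSON-serializable configuration consumed by the pipeline: the
#' generator settings (reference experimental design), analysis flags
#' (aggregation mode, correctness rule, attrition handling, bootstrap
#' settings), the optional risk-band overrides, and the master seed.
#'
#' @return A nested list.
#' @export
default_study_config <- function() {
  cfg <- generator_config()
  list(
    master_seed = 1L,
    generator = list(
      n_trials = cfg$n_trials, n_network = cfg$n_network,
      n_control = cfg$n_control, degree = cfg$degree,
      arms = lapply(cfg$arms, function(a)
        list(estimate_mean = a$estimate_mean, estimate_sd = a$estimate_sd,
             choice_probs = as.list(a$choice_probs))),
      choice_model = list(slope = cfg$choice_model$slope,
                          intercepts = as.list(cfg$choice_model$intercepts),
                          switch_prob = cfg$choice_model$switch_prob),
      revision = cfg$revision,
      control = cfg$control,
      completion_prob = cfg$completion_prob),
    analysis = list(
      aggregate = "trial",
      correctness_rule = list("C"),
      attrition = "complete_case",
      bootstrap = list(group_size = 40L, n_groups = 1L)),
    risk_bands = list(low = NA, high = NA))
}

check_known_keys <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
}

merge_config <- function(base, override, where = "config") {
  check_known_keys(override, names(base), where)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste(where, nm, sep = "$"))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a study configuration from JSON
#'
#' Values omitted from the file fall back to [default_study_config()];
#' unknown keys are rejected.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return A validated configuration list.
#' @export
read_study_config <- function(path = NULL) {
  base <- default_study_config()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg <- merge_config(base, user)
  stopifnot(cfg$analysis$aggregate %in% c("trial", "pooled"),
            cfg$analysis$attrition %in% c("complete_case", "locf"))
  correctness_rule(unlist(cfg$analysis$correctness_rule))  # validates
  cfg
}

#' Write a study configuration to JSON
#'
#' @param config configuration list.
#' @param path output path.
#' @export
write_study_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

# Build a generator_config from the config list, with an optional seed
# override.
config_to_generator <- function(config, seed = NULL) {
  g <- config$generator
  generator_config(
    n_trials = g$n_trials, n_network = g$n_network, n_control = g$n_control,
    degree = g$degree,
    arms = lapply(g$arms, function(a)
      arm_config(a$estimate_mean, a$estimate_sd, unlist(a$choice_probs))),
    choice_model = list(slope = g$choice_model$slope,
                        intercepts = unlist(g$choice_model$intercepts),
                        switch_prob = g$choice_model$switch_prob),
    revision = g$revision, control = g$control,
    completion_prob = g$completion_prob,
    master_seed = if (is.null(seed)) config$master_seed else as.integer(seed))
}

# ---- reporting ------------------------------------------------------------

write_analysis_outputs <- function(analysis, records, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(analysis$observations,
                   file.path(out_dir, "trial_observations.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics_table(records, analysis$rule),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(analysis$tests, file.path(out_dir, "tests.csv"),
                   row.names = FALSE)
  summary <- list(
    n_observations = nrow(analysis$observations),
    revision = analysis$revision[c("r", "se", "n")],
    improvement_network = analysis$improvement_network[
      c("delta_pp", "rate_a", "rate_b", "n_used", "n_excluded")],
    inequity = lapply(analysis$inequity, function(iq)
      list(gap = as.list(iq$gap), inequity = iq$inequity)),
    odds_ratios = lapply(analysis$odds_ratios, function(o)
      if (is.null(o)) NULL else as.list(o[2L, c("term", "or", "or_lo",
                                                "or_hi", "p")])))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(out_dir)
}

render_report <- function(results_dir) {
  obs <- utils::read.csv(file.path(results_dir, "trial_observations.csv"))
  tests <- utils::read.csv(file.path(results_dir, "tests.csv"))
  summ <- jsonlite::fromJSON(file.path(results_dir, "summary.json"))
  fmt_cell <- function(cond) {
    sub <- obs[obs$condition == cond, ]
    vapply(ARM_LEVELS, function(a) {
      s <- sub[sub$arm == a, ]
      sprintf("  %-14s %-12s accuracy %.3f -> %.3f | guideline %4.1f%% -> %4.1f%% | A-C gap %+6.1f -> %+6.1f pp",
              cond, a, mean(s$acc_initial), mean(s$acc_final),
              100 * mean(s$correct_initial), 100 * mean(s$correct_final),
              mean(s$gap_initial_pp), mean(s$gap_final_pp))
    }, character(1))
  }
  lines <- c(
    "Clinician peer-network study report",
    "===================================",
    sprintf("Trial-level observations: %d", summ$n_observations),
    "",
    "Per-condition means across trials (initial -> final):",
    fmt_cell("control"), fmt_cell("network"), "",
    sprintf("Revision coefficient (network clinicians): r = %.2f (SE %.2f, n = %d)",
            summ$revision$r, summ$revision$se, summ$revision$n),
    sprintf("Guideline-rate improvement in networks: %+.1f pp (%.0f%% -> %.0f%%)",
            summ$improvement_network$delta_pp,
            100 * summ$improvement_network$rate_a,
            100 * summ$improvement_network$rate_b),
    sprintf("Inequity (pp): initial %+.1f; final network %+.1f; final control %+.1f",
            summ$inequity$initial$inequity,
            summ$inequity$final_network$inequity,
            summ$inequity$final_control$inequity),
    "",
    "Nonparametric contrasts (trial-level):",
    sprintf("  %-40s p = %.3f (n = %d)", tests$contrast, tests$p, tests$n))
  lines
}

# ---- command line ---------------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: clinnet <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate --out FILE [--config FILE] [--seed INT]",
    "      simulate a study and write the trial-data CSV",
    "  analyze  --data FILE --out DIR [--config FILE] [--sensitivity bc]",
    "      analyse a trial-data CSV into a results directory",
    "  report   --results DIR --out FILE",
    "      render a plain-text report from a results directory",
    sep = "\n")
}

parse_cli_args <- function(argv, spec) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    flag <- argv[i]
    if (!flag %in% names(spec))
      stop("unknown option: ", flag, call. = FALSE)
    if (i + 1L > length(argv))
      stop("option ", flag, " requires a value", call. = FALSE)
    opts[[spec[[flag]]]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (generate a synthetic study CSV), `analyze`
#' (run the trial-level analysis, optionally with the B+C sensitivity
#' rule), and `report` (plain-text summary). Parameters and seeds are
#' logged to standard error. Returns the exit code instead of quitting so
#' it can be driven from tests; the installed `exec/clinnet` script wraps
#' it with `quit()`.
#'
#' @param argv character vector of command-line arguments (default: the
#'   process's trailing arguments).
#' @return Integer exit code, invisibly: 0 on success, 2 on usage errors,
#'   1 on runtime failures.
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L || argv[1L] %in% c("-h", "--help", "help")) {
    message(cli_usage())
    return(invisible(if (length(argv) == 0L) 2L else 0L))
  }
  sub <- argv[1L]
  rest <- argv[-1L]
  run <- function(expr) {
    tryCatch({ expr; invisible(0L) },
             error = function(e) {
               message("error: ", conditionMessage(e))
               invisible(1L)
             })
  }
  if (sub == "simulate") {
    opts <- tryCatch(
      parse_cli_args(rest, c("--config" = "config", "--out" = "out",
                             "--seed" = "seed")),
      error = function(e) e)
    if (inherits(opts, "error") || is.null(opts$out)) {
      message(cli_usage())
      return(invisible(2L))
    }
    return(run({
      config <- read_study_config(opts$config)
      cfg <- config_to_generator(config, opts$seed)
      message("clinnet simulate: master_seed = ", cfg$master_seed)
      message("resolved config: ",
              jsonlite::toJSON(default_study_config_from(cfg, config),
                               auto_unbox = TRUE, digits = NA, na = "null"))
      write_trial_csv(simulate_study(cfg), opts$out)
      message("wrote ", opts$out)
    }))
  }
  if (sub == "analyze") {
    opts <- tryCatch(
      parse_cli_args(rest, c("--data" = "data", "--config" = "config",
                             "--out" = "out",
                             "--sensitivity" = "sensitivity")),
      error = function(e) e)
    if (inherits(opts, "error") || is.null(opts$data) || is.null(opts$out)) {
      message(cli_usage())
      return(invisible(2L))
    }
    return(run({
      config <- read_study_config(opts$config)
      rule <- if (!is.null(opts$sensitivity) && opts$sensitivity == "bc")
        correctness_rule(c("B", "C"))
      else correctness_rule(unlist(config$analysis$correctness_rule))
      records <- read_trial_csv(opts$data)
      message("clinnet analyze: ", nrow(records), " records; rule {",
              paste(rule$accepted, collapse = ","), "}; bootstrap seed ",
              config$master_seed)
      analysis <- analyze_study(
        records, rule = rule,
        group_size = config$analysis$bootstrap$group_size,
        n_groups = config$analysis$bootstrap$n_groups,
        bootstrap_seed = config$master_seed,
        attrition = config$analysis$attrition)
      write_analysis_outputs(analysis, records, opts$out)
      message("wrote results to ", opts$out)
    }))
  }
  if (sub == "report") {
    opts <- tryCatch(
      parse_cli_args(rest, c("--results" = "results", "--out" = "out")),
      error = function(e) e)
    if (inherits(opts, "error") || is.null(opts$results) ||
        is.null(opts$out)) {
      message(cli_usage())
      return(invisible(2L))
    }
    return(run({
      writeLines(render_report(opts$results), opts$out)
      message("wrote ", opts$out)
    }))
  }
  message("unknown subcommand: ", sub, "\n", cli_usage())
  invisible(2L)
}

# Resolved-config echo for the simulate log: the defaults overlaid with the
# generator actually used (so every CSV is reproducible from its log).
default_study_config_from <- function(cfg, config) {
  config$master_seed <- cfg$master_seed
  config$generator$completion_prob <- cfg$completion_prob
  config
}
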