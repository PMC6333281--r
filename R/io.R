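trial_schemas <- list(
  normality = list(
    cols = c(participant_id = "c", food_id = "c", size = "d", rep = "i",
             response = "i"),
    check = function(df) {
      bad <- which(!df$response %in% c(0L, 1L))
      if (length(bad) > 0) {
        sprintf("row %d: `response` must be 0 or 1 (got %s)",
                bad, df$response[bad])
      } else character(0)
    }
  ),
  intention = list(
    cols = c(participant_id = "c", food_id = "c", size = "d", rating = "i"),
    check = function(df) {
      bad <- which(!df$rating %in% 1:7)
      if (length(bad) > 0) {
        sprintf("row %d: `rating` must be an integer in 1..7 (got %s)",
                bad, df$rating[bad])
      } else character(0)
    }
  ),
  sizejudgment = list(
    cols = c(participant_id = "c", food_id = "c", small = "d", large = "d",
             rep = "i", larger_side = "c", response_side = "c",
             correct = "i", rt_ms = "d"),
    check = function(df) {
      msgs <- character(0)
      bad <- which(!df$correct %in% c(0L, 1L))
      if (length(bad) > 0) {
        msgs <- c(msgs, sprintf("row %d: `correct` must be 0 or 1", bad))
      }
      bad <- which(!(df$rt_ms > 0))
      if (length(bad) > 0) {
        msgs <- c(msgs, sprintf("row %d: `rt_ms` must be positive", bad))
      }
      bad <- which(!df$larger_side %in% c("left", "right") |
                     !df$response_side %in% c("left", "right"))
      if (length(bad) > 0) {
        msgs <- c(msgs, sprintf("row %d: sides must be 'left' or 'right'", bad))
      }
      msgs
    }
  )
)

#' Read a validated trial table
#'
#' Reads one of the three comma-separated trial tables (normality judgments,
#' intention ratings, relative size judgments), enforcing the exact schema:
#' unknown or missing columns and out-of-range values are rejected with
#' row-numbered messages.
#'
#' @param path CSV file path.
#' @param kind `"normality"`, `"intention"` or `"sizejudgment"`.
#' @return A typed tibble.
#' @export
read_trials <- function(path, kind = c("normality", "intention", "sizejudgment")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  schema <- trial_schemas[[kind]]
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_trials(df, kind, context = path)
  df <- df[names(schema$cols)]
  for (nm in names(schema$cols)) {
    df[[nm]] <- switch(schema$cols[[nm]],
                       c = as.character(df[[nm]]),
                       d = as.numeric(df[[nm]]),
                       i = as.integer(df[[nm]]))
  }
  rlang::inform(sprintf(
    "%s: %d rows, %d participants, %d foods.", basename(path), nrow(df),
    dplyr::n_distinct(df$participant_id), dplyr::n_distinct(df$food_id)
  ))
  dplyr::as_tibble(df)
}

#' @rdname read_trials
#' @param trials Trial tibble to validate or write.
#' @export
validate_trials <- function(trials, kind = c("normality", "intention", "sizejudgment"),
                            context = "trials") {
  kind <- match.arg(kind)
  schema <- trial_schemas[[kind]]
  missing <- setdiff(names(schema$cols), names(trials))
  extra <- setdiff(names(trials), names(schema$cols))
  if (length(missing) > 0 || length(extra) > 0) {
    rlang::abort(sprintf(
      "%s: header mismatch for kind '%s'%s%s.", context, kind,
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")) else ""
    ))
  }
  msgs <- schema$check(trials)
  if (length(msgs) > 0) {
    rlang::abort(sprintf("%s: invalid values:\n%s", context,
                         paste(utils::head(msgs, 10), collapse = "\n")))
  }
  invisible(trials)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path, kind = c("normality", "intention", "sizejudgment")) {
  kind <- match.arg(kind)
  validate_trials(trials, kind, context = path)
  readr::write_csv(trials[names(trial_schemas[[kind]]$cols)], path)
  invisible(path)
}

#' Run configuration for the full pipeline
#'
#' Bundles the analysis constants (majority threshold 0.60, pair increment
#' 20%, Likert midpoint 4, RT floor 350 ms, 3 SD outlier bound, familywise
#' alpha 0.05 with per-family comparison counts) with a [cohort_config()]
#' block for simulation runs. `run_config()` builds one in code;
#' `read_run_config()` loads the same structure from a YAML file whose
#' top-level keys mirror the argument names (with a nested `cohort` block).
#'
#' @param threshold Clear-majority criterion. Default 0.6.
#' @param delta_pct Pair increment, percent. Default 20.
#' @param midpoint Likert midpoint. Default 4.
#' @param floor_ms,k_sd RT trimming parameters. Defaults 350 and 3.
#' @param alpha Familywise alpha. Default 0.05.
#' @param kappa_midpoint,kappa_pairwise Comparison counts for the two
#'   Bonferroni families (midpoint t-tests; follow-up pairwise contrasts).
#' @param gg_correction Apply the Greenhouse-Geisser correction? Default
#'   `TRUE`.
#' @param log_rt Run the log-RT sensitivity ANOVA too? Default `FALSE`.
#' @param range_scope `"individual"` (repeated judgments) or `"collective"`.
#' @param study Stimulus design for simulation, 1 or 2. Default 2.
#' @param cohort A [cohort_config()] for simulation runs.
#' @param seed Overrides `cohort$seed` when given.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(threshold = 0.6, delta_pct = 20, midpoint = 4,
                       floor_ms = 350, k_sd = 3, alpha = 0.05,
                       kappa_midpoint = 6, kappa_pairwise = 1,
                       gg_correction = TRUE, log_rt = FALSE,
                       range_scope = c("individual", "collective"),
                       study = 2, cohort = cohort_config(), seed = NULL) {
  range_scope <- match.arg(range_scope)
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  check_threshold(threshold)
  stopifnot(delta_pct > 0, floor_ms > 0, k_sd > 0,
            alpha > 0, alpha < 1, kappa_midpoint >= 1, kappa_pairwise >= 1)
  structure(list(
    threshold = threshold, delta_pct = delta_pct, midpoint = midpoint,
    floor_ms = floor_ms, k_sd = k_sd, alpha = alpha,
    kappa_midpoint = kappa_midpoint, kappa_pairwise = kappa_pairwise,
    gg_correction = gg_correction, log_rt = log_rt,
    range_scope = range_scope, study = study, cohort = cohort
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort_args <- raw$cohort %||% list()
  raw$cohort <- NULL
  args <- raw
  args$cohort <- do.call(cohort_config, cohort_args)
  do.call(run_config, args)
}

#' Run the full simulate-and-analyse pipeline
#'
#' Chains every stage on a synthetic cohort: simulate the three trial tables,
#' estimate norm ranges (individual or collective per the config), build
#' category means and run the midpoint tests and intention ANOVA, build pair
#' difference scores and run the sensitivity ANOVA, trim RTs and run the
#' boundary discrimination ANOVAs and the Weber/categorical decomposition.
#' Fully deterministic given the config seed. When `out_dir` is given, all
#' trial and result tables are written as CSV plus a JSON summary.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return A named list bundle with the simulated tables, ranges, every
#'   analysis object, and a `log` tibble of exclusion counts.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }
  grid <- study_grids(config$study)
  sim <- stage("simulate", simulate_cohort(config$cohort, grid,
                                           delta_pct = config$delta_pct))
  ranges <- stage("estimate-norms", {
    if (config$range_scope == "individual") {
      individual_norm_ranges(sim$normality, threshold = config$threshold)
    } else {
      collective_norm_range(sim$normality, threshold = config$threshold)
    }
  })
  cat_means <- stage("classify", category_means(sim$intention, ranges))
  midpoint <- stage("analyze-intentions",
                    midpoint_tests(cat_means, kappa = config$kappa_midpoint,
                                   alpha = config$alpha,
                                   midpoint = config$midpoint))
  intent <- stage("analyze-intentions",
                  intention_anova(cat_means, correction = config$gg_correction,
                                  alpha_pairwise = config$alpha / config$kappa_pairwise))
  diffs <- stage("analyze-sensitivity",
                 pair_differences(sim$intention, sim$pairs, ranges))
  sensitivity <- stage("analyze-sensitivity",
                       sensitivity_anova(diffs, correction = config$gg_correction,
                                         alpha_pairwise = config$alpha / config$kappa_pairwise))
  trim <- stage("analyze-discrimination",
                trim_rts(sim$sizejudgment, floor_ms = config$floor_ms,
                         k_sd = config$k_sd))
  perf <- stage("analyze-discrimination", pair_performance(trim$trials))
  boundary <- stage("analyze-discrimination",
                    performance_by_boundary(perf, ranges,
                                            correction = config$gg_correction,
                                            log_rt = config$log_rt))
  decomposition <- stage("analyze-discrimination",
                         weber_categorical_decomposition(trim$trials, ranges))

  log <- tibble::tibble(
    stage = c("category_means", "pair_differences", "pair_differences",
              "trim_rts", "trim_rts", "boundary_performance", "decomposition"),
    what = c("participant-food cells without valid range",
             "pairs outside analysed categories",
             "pairs with missing ratings",
             "trials below RT floor", "trials above outlier bound",
             "pairs outside analysed categories",
             "participants flagged in decomposition"),
    n = c(attr(cat_means, "n_skipped") %||% 0L,
          attr(diffs, "n_excluded_pairs") %||% 0L,
          attr(diffs, "n_skipped_missing") %||% 0L,
          trim$report$n_removed_floor, trim$report$n_removed_outlier,
          boundary$n_excluded_pairs, decomposition$n_flagged)
  )

  bundle <- list(
    config = config, panel = sim$panel, grid = sim$grid, pairs = sim$pairs,
    normality = sim$normality, intention = sim$intention,
    sizejudgment = sim$sizejudgment, ranges = ranges,
    category_means = cat_means, midpoint_tests = midpoint,
    intention_anova = intent, pair_differences = diffs,
    sensitivity_anova = sensitivity, trim = trim, pair_performance = perf,
    boundary_performance = boundary, decomposition = decomposition,
    log = log
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_trials(bundle$normality, p("normality.csv"), "normality")
  write_trials(bundle$intention, p("intention.csv"), "intention")
  write_trials(bundle$sizejudgment, p("sizejudgment.csv"), "sizejudgment")
  readr::write_csv(bundle$ranges, p("norm_ranges.csv"))
  readr::write_csv(bundle$category_means, p("category_means.csv"))
  readr::write_csv(bundle$midpoint_tests, p("midpoint_tests.csv"))
  readr::write_csv(tidy(bundle$intention_anova), p("intention_anova.csv"))
  readr::write_csv(bundle$intention_anova$pairwise, p("intention_pairwise.csv"))
  readr::write_csv(bundle$pair_differences, p("pair_differences.csv"))
  readr::write_csv(tidy(bundle$sensitivity_anova), p("sensitivity_anova.csv"))
  readr::write_csv(bundle$trim$report, p("trim_report.csv"))
  readr::write_csv(bundle$pair_performance, p("pair_performance.csv"))
  readr::write_csv(tidy(bundle$boundary_performance$accuracy),
                   p("boundary_accuracy_anova.csv"))
  readr::write_csv(tidy(bundle$boundary_performance$rt),
                   p("boundary_rt_anova.csv"))
  readr::write_csv(bundle$decomposition$summary, p("decomposition.csv"))
  readr::write_csv(bundle$log, p("run_log.csv"))
  summary <- list(
    seed = bundle$config$cohort$seed,
    n_participants = bundle$config$cohort$n_participants,
    range_scope = bundle$config$range_scope,
    n_valid_ranges = sum(bundle$ranges$valid),
    trim_loss_pct = 100 * bundle$trim$report$loss_proportion,
    log = bundle$log
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
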