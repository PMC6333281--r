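#' Trim reaction times: anticipatory floor, then outlier bound
#'
#' Two-stage trimming of relative size judgment trials. Trials faster than
#' `floor_ms` (anticipatory responses) are removed first; the mean and SD of
#' the remaining RTs are then computed — pooled over the whole sample by
#' default, since the outlier bound is a single sample-level threshold — and
#' trials slower than `mean + k_sd * SD` are removed. Accuracy analyses use
#' the retained trials too: trimming drops whole trials, not just their RTs.
#'
#' @param trials Size-judgment tibble (must contain `rt_ms`).
#' @param floor_ms Anticipatory floor, milliseconds. Default 350.
#' @param k_sd Outlier bound in SD units. Default 3.
#' @param scope `"pooled"` (one threshold for the whole sample, default) or
#'   `"participant"` (threshold per participant).
#' @return A list of class `nr_trim`: `trials` (retained rows) and `report`
#'   (one-row tibble: `n_input`, `n_removed_floor`, `n_removed_outlier`,
#'   `loss_proportion`, `threshold_ms`, plus the pooled `mean_ms` and
#'   `sd_ms`; `threshold_ms` is `NA` for per-participant scope).
#' @export
trim_rts <- function(trials, floor_ms = 350, k_sd = 3,
                     scope = c("pooled", "participant")) {
  scope <- match.arg(scope)
  stopifnot(floor_ms > 0, k_sd > 0)
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    rlang::abort("`trials` must be a non-empty data frame.")
  }
  n_input <- nrow(trials)
  kept <- dplyr::filter(trials, .data$rt_ms >= floor_ms)
  n_floor <- n_input - nrow(kept)
  if (scope == "pooled") {
    thr <- mean(kept$rt_ms) + k_sd * stats::sd(kept$rt_ms)
    if (is.na(thr)) thr <- Inf  # a single retained trial has no SD
    retained <- dplyr::filter(kept, .data$rt_ms <= thr)
    report_thr <- thr
    pooled_mean <- mean(kept$rt_ms)
    pooled_sd <- stats::sd(kept$rt_ms)
  } else {
    kept <- kept |>
      dplyr::mutate(.thr = stats::ave(.data$rt_ms, .data$participant_id,
                                      FUN = function(x) mean(x) + k_sd * stats::sd(x)))
    retained <- kept |>
      dplyr::filter(.data$rt_ms <= .data$.thr) |>
      dplyr::select(-".thr")
    kept <- dplyr::select(kept, -".thr")
    report_thr <- NA_real_
    pooled_mean <- mean(kept$rt_ms)
    pooled_sd <- stats::sd(kept$rt_ms)
  }
  n_outlier <- nrow(kept) - nrow(retained)
  report <- tibble::tibble(
    n_input = n_input,
    n_removed_floor = n_floor,
    n_removed_outlier = n_outlier,
    loss_proportion = (n_floor + n_outlier) / n_input,
    threshold_ms = report_thr,
    mean_ms = pooled_mean,
    sd_ms = pooled_sd
  )
  structure(list(trials = retained, report = report), class = "nr_trim")
}

#' @export
print.nr_trim <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "RT trimming: %d trials in, %d below floor, %d above %s ms bound (loss %.2f%%)\n",
    r$n_input, r$n_removed_floor, r$n_removed_outlier,
    ifelse(is.na(r$threshold_ms), "per-participant", sprintf("%.0f", r$threshold_ms)),
    100 * r$loss_proportion
  ))
  invisible(x)
}

#' Per-pair discrimination performance
#'
#' Accuracy (proportion correct over retained trials) and mean RT of correct
#' retained trials, per participant x food x pair. Cells whose retained
#' trials are all incorrect get a missing RT; their count is attached as the
#' attribute `n_rt_missing`.
#'
#' @param trials Retained size-judgment tibble (e.g. `trim_rts(...)$trials`).
#' @return Tibble `participant_id`, `food_id`, `small`, `large`, `accuracy`,
#'   `mean_rt_correct`, `n_trials`.
#' @export
pair_performance <- function(trials) {
  stopifnot(all(c("participant_id", "food_id", "small", "large",
                  "correct", "rt_ms") %in% names(trials)))
  out <- trials |>
    dplyr::summarise(
      accuracy = mean(.data$correct),
      mean_rt_correct = if (any(.data$correct == 1))
        mean(.data$rt_ms[.data$correct == 1]) else NA_real_,
      n_trials = dplyr::n(),
      .by = c("participant_id", "food_id", "small", "large")
    )
  n_missing <- sum(is.na(out$mean_rt_correct))
  if (n_missing > 0) {
    rlang::inform(sprintf(
      "pair_performance: %d cell(s) have no correct trials; RT set to NA.", n_missing
    ))
  }
  attr(out, "n_rt_missing") <- n_missing
  out
}

#' Discrimination performance by norm-range boundary category
#'
#' Classifies each performance pair against the applicable norm range,
#' averages accuracy and correct-trial RT per participant x food x boundary
#' category (across lower boundary / within range / across upper boundary),
#' and runs the category x food repeated-measures ANOVA with adjacent
#' pairwise contrasts separately for accuracy and RT. Categorical perception
#' predicts better accuracy and faster RT for boundary-crossing pairs. An
#' optional natural-log RT rerun is included as a skewness sensitivity
#' check.
#'
#' @param perf Output of [pair_performance()].
#' @param ranges Norm-range tibble.
#' @param correction,alpha_pairwise,followup_alpha See [intention_anova()].
#' @param log_rt Also run the ANOVA on `log(mean RT)`? Default `FALSE`.
#' @return A list of class `nr_boundary_perf`: `means` (category means
#'   tibble), `accuracy` and `rt` (`nr_analysis` objects), optionally
#'   `rt_log`, and `n_excluded_pairs`.
#' @export
performance_by_boundary <- function(perf, ranges, correction = TRUE,
                                    alpha_pairwise = 0.05,
                                    followup_alpha = 0.05, log_rt = FALSE) {
  classified <- join_ranges(perf, ranges) |>
    dplyr::filter(!is.na(.data$valid) & .data$valid) |>
    dplyr::mutate(boundary_category = classify_pair(.data$small, .data$large,
                                                    .data$lower, .data$upper))
  analysed <- c("across_lower", "within", "across_upper")
  n_excl <- sum(!classified$boundary_category %in% analysed)
  means <- classified |>
    dplyr::filter(.data$boundary_category %in% analysed) |>
    dplyr::mutate(boundary_category = factor(.data$boundary_category,
                                             levels = analysed)) |>
    dplyr::summarise(
      accuracy = mean(.data$accuracy),
      mean_rt = mean(.data$mean_rt_correct, na.rm = TRUE),
      n_pairs = dplyr::n(),
      .by = c("participant_id", "food_id", "boundary_category")
    )
  adjacent <- list(c("across_lower", "within"), c("within", "across_upper"))
  acc <- run_category_analysis(means, value_col = "accuracy",
                               category_col = "boundary_category",
                               correction = correction,
                               alpha_pairwise = alpha_pairwise,
                               followup_alpha = followup_alpha,
                               adjacent = adjacent)
  rt_means <- dplyr::filter(means, is.finite(.data$mean_rt))
  rt <- run_category_analysis(rt_means, value_col = "mean_rt",
                              category_col = "boundary_category",
                              correction = correction,
                              alpha_pairwise = alpha_pairwise,
                              followup_alpha = followup_alpha,
                              adjacent = adjacent)
  out <- list(means = means, accuracy = acc, rt = rt,
              n_excluded_pairs = n_excl)
  if (log_rt) {
    out$rt_log <- run_category_analysis(
      dplyr::mutate(rt_means, mean_rt = log(.data$mean_rt)),
      value_col = "mean_rt", category_col = "boundary_category",
      correction = correction, alpha_pairwise = alpha_pairwise,
      followup_alpha = followup_alpha, adjacent = adjacent
    )
  }
  structure(out, class = "nr_boundary_perf")
}

#' @export
print.nr_boundary_perf <- function(x, ...) {
  cat("Discrimination by boundary category\n\n== Accuracy ==\n")
  print(x$accuracy)
  cat("\n== Correct-trial RT ==\n")
  print(x$rt)
  if (!is.null(x$rt_log)) cat("\n(log-RT sensitivity rerun included)\n")
  invisible(x)
}

#' Weber-versus-categorical decomposition of discrimination accuracy
#'
#' Asks whether discrimination is locked to the norm-range boundaries beyond
#' what Weber's law predicts. For each participant, trial-level correctness
#' is modelled by a logistic regression on the Weber predictor
#' `delta / mean_size` and an indicator of whether the pair crosses a
#' boundary of that participant's estimated norm range; a parallel linear
#' model of log RT runs on correct trials. Coefficients are summarised
#' across participants (mean, SE of the mean, one-sample t). A positive
#' crossing coefficient with the Weber coefficient controlled is the
#' signature of categorical perception; a positive Weber coefficient alone
#' says performance tracks relative size difference.
#'
#' Participants whose model fails to converge, shows separation (inflated
#' coefficient standard errors), or lacks both crossing and non-crossing
#' pairs are flagged and excluded from the summary.
#'
#' @param trials Retained size-judgment tibble.
#' @param ranges Norm-range tibble (typically individual estimated ranges;
#'   pass generator truth for a diagnostic run).
#' @param se_cap Per-participant coefficient SE above which a logistic fit
#'   is treated as separated and excluded. Default 50.
#' @return A list of class `nr_decomposition`: `summary` (one row per model
#'   x term: `model`, `term`, `estimate` = across-participant mean, `se`,
#'   `statistic`, `df`, `p_value`, `n_participants`), `coefficients`
#'   (per-participant), `n_flagged`.
#' @export
weber_categorical_decomposition <- function(trials, ranges, se_cap = 50) {
  dat <- join_ranges(trials, ranges) |>
    dplyr::filter(!is.na(.data$valid) & .data$valid) |>
    dplyr::mutate(
      weber = .data$large - .data$small,
      weber = .data$weber / ((.data$small + .data$large) / 2),
      crossing = as.integer(
        classify_pair(.data$small, .data$large, .data$lower, .data$upper) %in%
          c("across_lower", "across_upper", "spanning")
      )
    )
  fits <- dat |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(d, key) fit_participant_models(d, se_cap)) |>
    dplyr::ungroup()
  flagged <- fits |>
    dplyr::summarise(bad = any(.data$flagged), .by = "participant_id")
  usable <- flagged$participant_id[!flagged$bad]
  n_flagged <- sum(flagged$bad)
  if (n_flagged > 0) {
    rlang::inform(sprintf(
      "decomposition: %d participant(s) flagged (non-convergence/separation/no contrast) and excluded.",
      n_flagged
    ))
  }
  summary <- fits |>
    dplyr::filter(.data$participant_id %in% usable) |>
    dplyr::group_by(.data$model, .data$term) |>
    dplyr::group_modify(function(d, key) {
      res <- one_sample_t(d$estimate, mu0 = 0)
      tibble::tibble(estimate = mean(d$estimate),
                     se = res$se, statistic = res$statistic, df = res$df,
                     p_value = res$p_value, n_participants = nrow(d))
    }) |>
    dplyr::ungroup()
  structure(list(summary = summary, coefficients = fits,
                 n_flagged = n_flagged),
            class = "nr_decomposition")
}

fit_participant_models <- function(d, se_cap) {
  out <- list()
  if (dplyr::n_distinct(d$crossing) < 2 || dplyr::n_distinct(d$weber) < 2) {
    return(tibble::tibble(model = "accuracy_logistic", term = "crossing",
                          estimate = NA_real_, std_error = NA_real_,
                          flagged = TRUE))
  }
  fit <- suppressWarnings(
    stats::glm(correct ~ weber + crossing, family = stats::binomial(), data = d)
  )
  cf <- summary(fit)$coefficients
  acc_flag <- !fit$converged || any(cf[, "Std. Error"] > se_cap)
  out$acc <- tibble::tibble(
    model = "accuracy_logistic",
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    flagged = acc_flag
  )
  dc <- d[d$correct == 1 & d$rt_ms > 0, ]
  if (nrow(dc) >= 5 && dplyr::n_distinct(dc$crossing) == 2 &&
      dplyr::n_distinct(dc$weber) >= 2) {
    lf <- stats::lm(log(rt_ms) ~ weber + crossing, data = dc)
    lc <- summary(lf)$coefficients
    out$rt <- tibble::tibble(
      model = "log_rt_linear",
      term = rownames(lc),
      estimate = lc[, "Estimate"],
      std_error = lc[, "Std. Error"],
      flagged = FALSE
    )
  }
  purrr::list_rbind(out)
}

#' @export
print.nr_decomposition <- function(x, ...) {
  cat("Weber vs categorical decomposition (across-participant summary)\n")
  print(dplyr::mutate(x$summary,
                      dplyr::across(c("estimate", "se", "statistic"),
                                    ~ round(.x, 3)),
                      p_value = signif(.data$p_value, 3)))
  if (x$n_flagged > 0) cat(sprintf("%d participant(s) flagged/excluded.\n", x$n_flagged))
  invisible(x)
}

#' @rdname weber_categorical_decomposition
#' @param x An `nr_decomposition` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nr_decomposition <- function(x, ...) x$summary

#' @rdname weber_categorical_decomposition
#' @exportS3Method generics::glance
glance.nr_decomposition <- function(x, ...) {
  tibble::tibble(
    n_participants = max(x$summary$n_participants),
    n_flagged = x$n_flagged
  )
}
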