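#' Mean intended consumption per portion-size category
#'
#' Joins each intention rating to the applicable norm range (collective
#' ranges join by food; individual ranges by participant and food),
#' classifies every rated size as below / within / above the range, and
#' averages ratings per participant x food x category. Each size contributes
#' once (both studies collected a single rating per size). Participants
#' without a valid range for a food are skipped, and the skipped count is
#' attached to the result.
#'
#' @param ratings Intention tibble (`participant_id`, `food_id`, `size`,
#'   `rating`).
#' @param ranges Norm-range tibble from [collective_norm_range()] or
#'   [individual_norm_ranges()].
#' @return A tibble `participant_id`, `food_id`, `category`, `mean_rating`,
#'   `n_sizes`, with attribute `n_skipped` (participant x food cells dropped
#'   for want of a valid range).
#' @export
category_means <- function(ratings, ranges) {
  joined <- join_ranges(ratings, ranges)
  skipped <- joined |>
    dplyr::filter(is.na(.data$valid) | !.data$valid) |>
    dplyr::distinct(.data$participant_id, .data$food_id)
  if (nrow(skipped) > 0) {
    rlang::inform(sprintf(
      "category_means: skipped %d participant-food cell(s) without a valid norm range.",
      nrow(skipped)
    ))
  }
  out <- joined |>
    dplyr::filter(!is.na(.data$valid) & .data$valid) |>
    dplyr::mutate(category = classify_portion(.data$size, .data$lower, .data$upper)) |>
    dplyr::summarise(mean_rating = mean(.data$rating), n_sizes = dplyr::n(),
                     .by = c("participant_id", "food_id", "category"))
  attr(out, "n_skipped") <- nrow(skipped)
  out
}

# Attach each row's applicable range; collective ranges apply to every
# participant of the food.
join_ranges <- function(tbl, ranges) {
  stopifnot(all(c("scope", "food_id", "lower", "upper", "valid") %in% names(ranges)))
  if (all(ranges$scope == "collective")) {
    dplyr::left_join(tbl, ranges[c("food_id", "lower", "upper", "valid")],
                     by = "food_id")
  } else if (all(ranges$scope == "individual")) {
    dplyr::left_join(tbl,
                     ranges[c("participant_id", "food_id", "lower", "upper", "valid")],
                     by = c("participant_id", "food_id"))
  } else {
    rlang::abort("`ranges` must be all-collective or all-individual.")
  }
}

#' Test category means against the Likert midpoint
#'
#' One-sample t-tests comparing the mean intended consumption in each food x
#' category cell with the scale midpoint (4 = eat the whole portion, no
#' more), at a Bonferroni-corrected level `alpha / kappa`. Cells with fewer
#' than two participants are skipped and counted.
#'
#' @param means Output of [category_means()].
#' @param kappa Number of comparisons in the family (15 for five foods x
#'   three categories).
#' @param alpha Familywise alpha. Default 0.05.
#' @param midpoint Null value. Default 4.
#' @return A tibble of test results, one row per food x category, with the
#'   corrected threshold in `alpha_adjusted`.
#' @export
midpoint_tests <- function(means, kappa = 15, alpha = 0.05, midpoint = 4) {
  adj <- bonferroni_alpha(alpha, kappa)$alpha_adjusted
  cells <- means |>
    dplyr::summarise(n = dplyr::n(), .by = c("food_id", "category"))
  small <- cells[cells$n < 2, ]
  if (nrow(small) > 0) {
    rlang::inform(sprintf("midpoint_tests: skipped %d cell(s) with < 2 participants.",
                          nrow(small)))
  }
  means |>
    dplyr::inner_join(cells[cells$n >= 2, c("food_id", "category")],
                      by = c("food_id", "category")) |>
    dplyr::group_by(.data$food_id, .data$category) |>
    dplyr::group_modify(~ one_sample_t(.x$mean_rating, mu0 = midpoint,
                                       alpha_adjusted = adj)) |>
    dplyr::ungroup()
}

#' Category x food repeated-measures ANOVA on intended consumption
#'
#' Runs the 3 (portion-size category) x k (food) within-subjects ANOVA on
#' the category means, keeping only participants with a complete category x
#' food design (listwise exclusion, counted). Adjacent category contrasts
#' (below vs within, within vs above) follow as paired comparisons, and a
#' significant interaction triggers per-food one-way follow-up ANOVAs. With
#' a single food the design collapses to a one-way ANOVA.
#'
#' @param means Output of [category_means()].
#' @param correction Greenhouse-Geisser correction flag, passed to
#'   [rm_anova()].
#' @param alpha_pairwise Significance threshold recorded with the pairwise
#'   contrasts. Default 0.05.
#' @param followup_alpha Threshold on the interaction p-value that triggers
#'   per-food follow-ups. Default 0.05.
#' @return A list of class `nr_analysis`: `anova` (an `nr_anova`),
#'   `pairwise` (tibble), `followup` (named list of per-food `nr_anova`, or
#'   `NULL`), `n_analyzed`, `n_excluded`.
#' @export
intention_anova <- function(means, correction = TRUE, alpha_pairwise = 0.05,
                            followup_alpha = 0.05) {
  run_category_analysis(means, value_col = "mean_rating",
                        category_col = "category",
                        correction = correction,
                        alpha_pairwise = alpha_pairwise,
                        followup_alpha = followup_alpha,
                        adjacent = list(c("below", "within"),
                                        c("within", "above")))
}

# Shared engine for the category x food analyses (intention, sensitivity,
# discrimination): listwise completion, two-way or collapsed one-way ANOVA,
# adjacent pairwise contrasts, per-food follow-ups on interaction.
run_category_analysis <- function(data, value_col, category_col, correction,
                                  alpha_pairwise, followup_alpha, adjacent) {
  cats <- levels(data[[category_col]])
  cats <- cats[cats %in% unique(as.character(data[[category_col]]))]
  foods <- unique(data$food_id)
  full <- length(cats) * length(foods)
  data <- dplyr::mutate(data, .cat = as.character(.data[[category_col]]))
  complete_ids <- data |>
    dplyr::distinct(.data$participant_id, .data$food_id, .data$.cat) |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n == full) |>
    dplyr::pull("participant_id")
  n_excluded <- dplyr::n_distinct(data$participant_id) - length(complete_ids)
  if (n_excluded > 0) {
    rlang::inform(sprintf(
      "%d participant(s) excluded listwise (incomplete category x food design).",
      n_excluded
    ))
  }
  kept <- dplyr::filter(data, .data$participant_id %in% complete_ids)
  if (length(complete_ids) < 2) {
    rlang::abort("Fewer than 2 listwise-complete participants; cannot run the ANOVA.")
  }
  within <- if (length(foods) > 1) c(".cat", "food_id") else ".cat"
  fit <- rm_anova(kept, dv = value_col, subject = "participant_id",
                  within = within, correction = correction)
  fit$table$effect <- sub("^\\.cat", category_col, fit$table$effect)

  pairwise <- purrr::map(adjacent, function(lv) {
    if (!all(lv %in% cats)) return(NULL)
    pairwise_within(kept, dv = value_col, subject = "participant_id",
                    factor = ".cat", levels = lv,
                    alpha_adjusted = alpha_pairwise)
  }) |> purrr::compact() |> purrr::list_rbind()

  followup <- NULL
  inter <- fit$table[grepl(":", fit$table$effect), ]
  if (nrow(inter) == 1 && inter$p_value < followup_alpha) {
    followup <- purrr::map(stats::setNames(foods, foods), function(f) {
      one <- rm_anova(dplyr::filter(kept, .data$food_id == f),
                      dv = value_col, subject = "participant_id",
                      within = ".cat", correction = correction)
      one$table$effect <- sub("^\\.cat", category_col, one$table$effect)
      one
    })
  }
  structure(list(anova = fit, pairwise = pairwise, followup = followup,
                 n_analyzed = length(complete_ids), n_excluded = n_excluded),
            class = "nr_analysis")
}

#' @export
print.nr_analysis <- function(x, ...) {
  print(x$anova)
  cat(sprintf("\n%d participant(s) analysed, %d excluded listwise.\n",
              x$n_analyzed, x$n_excluded))
  if (nrow(x$pairwise) > 0) {
    cat("\nAdjacent pairwise comparisons:\n")
    print(x$pairwise)
  }
  if (!is.null(x$followup)) {
    cat(sprintf("\nPer-food follow-up ANOVAs run for: %s\n",
                paste(names(x$followup), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname intention_anova
#' @param x An `nr_analysis` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nr_analysis <- function(x, ...) x$anova$table

#' @rdname intention_anova
#' @exportS3Method generics::glance
glance.nr_analysis <- function(x, ...) {
  tibble::tibble(n_analyzed = x$n_analyzed, n_excluded = x$n_excluded,
                 n_pairwise = nrow(x$pairwise),
                 followup = !is.null(x$followup))
}

#' Intended-consumption differences for fixed-increment pairs
#'
#' For every portion pair the difference score is `rating(small) -
#' rating(large)` — positive when intended consumption falls as the portion
#' grows. Pairs are classified by boundary position against the applicable
#' norm range, scores are averaged per participant x food x boundary
#' category, and only the three analysed categories (across the lower
#' boundary, within the range, across the upper boundary) are kept; pairs
#' entirely outside the range or spanning it are excluded and counted.
#'
#' @param ratings Intention tibble.
#' @param pairs Pair tibble from [build_pairs()].
#' @param ranges Norm-range tibble.
#' @return Tibble `participant_id`, `food_id`, `boundary_category`,
#'   `mean_diff`, `n_pairs`, with attributes `n_excluded_pairs` (pair rows
#'   outside the analysed categories) and `n_skipped_missing` (pairs lacking
#'   a member rating).
#' @export
pair_differences <- function(ratings, pairs, ranges) {
  per_pair <- pairs |>
    dplyr::cross_join(dplyr::distinct(ratings, .data$participant_id)) |>
    dplyr::left_join(dplyr::rename(ratings, small = "size", rating_small = "rating"),
                     by = c("participant_id", "food_id", "small")) |>
    dplyr::left_join(dplyr::rename(ratings, large = "size", rating_large = "rating"),
                     by = c("participant_id", "food_id", "large"))
  n_missing <- sum(is.na(per_pair$rating_small) | is.na(per_pair$rating_large))
  if (n_missing > 0) {
    rlang::inform(sprintf("pair_differences: %d pair(s) skipped for missing ratings.",
                          n_missing))
  }
  per_pair <- dplyr::filter(per_pair, !is.na(.data$rating_small),
                            !is.na(.data$rating_large))
  per_pair <- join_ranges(per_pair, ranges) |>
    dplyr::filter(!is.na(.data$valid) & .data$valid) |>
    dplyr::mutate(
      boundary_category = classify_pair(.data$small, .data$large,
                                        .data$lower, .data$upper),
      diff = .data$rating_small - .data$rating_large
    )
  analysed <- c("across_lower", "within", "across_upper")
  n_excl <- sum(!per_pair$boundary_category %in% analysed)
  out <- per_pair |>
    dplyr::filter(.data$boundary_category %in% analysed) |>
    dplyr::mutate(boundary_category = factor(.data$boundary_category,
                                             levels = analysed)) |>
    dplyr::summarise(mean_diff = mean(.data$diff), n_pairs = dplyr::n(),
                     .by = c("participant_id", "food_id", "boundary_category"))
  attr(out, "n_excluded_pairs") <- n_excl
  attr(out, "n_skipped_missing") <- n_missing
  out
}

#' Boundary-sensitivity repeated-measures ANOVA
#'
#' Compares the mean intended-consumption difference scores across the three
#' boundary categories (across lower boundary, within range, across upper
#' boundary) and foods in a within-subjects ANOVA with adjacent pairwise
#' contrasts, mirroring [intention_anova()]. Larger differences mean
#' intended consumption is more sensitive to a fixed 20%-of-reference size
#' change at that position.
#'
#' @param diffs Output of [pair_differences()].
#' @inheritParams intention_anova
#' @return An `nr_analysis` list (see [intention_anova()]).
#' @export
sensitivity_anova <- function(diffs, correction = TRUE, alpha_pairwise = 0.05,
                              followup_alpha = 0.05) {
  run_category_analysis(diffs, value_col = "mean_diff",
                        category_col = "boundary_category",
                        correction = correction,
                        alpha_pairwise = alpha_pairwise,
                        followup_alpha = followup_alpha,
                        adjacent = list(c("across_lower", "within"),
                                        c("within", "across_upper")))
}
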