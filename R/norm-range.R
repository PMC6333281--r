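#' Collective norm range by the clear-majority rule
#'
#' For each food, the lower boundary of the collective norm range is the
#' smallest portion size judged "normal" by a clear majority of participants
#' and the upper boundary the largest such size, where a clear majority is at
#' least `ceiling(threshold * N)` participants (36 of 60 at the default
#' threshold of 0.60). When participants contributed repeated judgments, each
#' participant is first reduced to a binary per-size verdict by the same
#' threshold applied to their repetitions, keeping the single-judgment and
#' repeated-judgment collective paths structurally identical.
#'
#' Interior sizes that fall short of the majority do not shrink the range
#' (the rule defines only the smallest and largest qualifying size); any such
#' non-contiguity is reported with a warning.
#'
#' @param judgments Normality judgment tibble (`participant_id`, `food_id`,
#'   `size`, `rep`, `response`).
#' @param threshold Majority criterion, a proportion in (0.5, 1]. Default 0.6.
#' @return A tibble with one row per food: `scope` (`"collective"`),
#'   `participant_id` (`NA`), `food_id`, `lower`, `upper`, `valid`,
#'   `n_basis` (number of participants).
#' @export
collective_norm_range <- function(judgments, threshold = 0.6) {
  check_threshold(threshold)
  check_judgments(judgments)
  verdicts <- judgments |>
    dplyr::summarise(
      normal = mean(.data$response) >= threshold - 1e-9,
      .by = c("participant_id", "food_id", "size")
    )
  verdicts |>
    dplyr::group_by(.data$food_id) |>
    dplyr::group_modify(function(v, key) {
      n <- dplyr::n_distinct(v$participant_id)
      votes <- v |>
        dplyr::summarise(count = sum(.data$normal), .by = "size")
      # ceiling() guard: 0.7 * 10 exceeds 7 in double arithmetic
      majority_range(votes$size, votes$count >= ceiling(threshold * n - 1e-9),
                     n_basis = n, label = key$food_id)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(scope = "collective", participant_id = NA_character_,
                  .before = 1) |>
    dplyr::relocate("food_id", .after = "participant_id")
}

#' Individual norm ranges from repeated judgments
#'
#' For each participant and food, a size qualifies as "normal" when its
#' normal-judgment proportion over repetitions is at least `threshold`
#' (6 of 10 at the default); the range runs from the smallest to the largest
#' qualifying size. Participants for whom no size qualifies get an invalid
#' range and are excluded from downstream analyses (their counts are
#' reported by the analysis stages).
#'
#' @inheritParams collective_norm_range
#' @return A tibble with one row per participant x food: `scope`
#'   (`"individual"`), `participant_id`, `food_id`, `lower`, `upper`,
#'   `valid`, `n_basis` (repetitions per size).
#' @export
individual_norm_ranges <- function(judgments, threshold = 0.6) {
  check_threshold(threshold)
  check_judgments(judgments)
  n_sizes <- judgments |>
    dplyr::distinct(.data$food_id, .data$size) |>
    dplyr::count(.data$food_id, name = "n_grid")
  complete <- judgments |>
    dplyr::distinct(.data$participant_id, .data$food_id, .data$size) |>
    dplyr::count(.data$participant_id, .data$food_id, name = "n_seen") |>
    dplyr::left_join(n_sizes, by = "food_id")
  if (any(complete$n_seen != complete$n_grid)) {
    bad <- complete[complete$n_seen != complete$n_grid, ]
    rlang::abort(sprintf(
      "Incomplete design: %d participant-food cell(s) are missing sizes (e.g. %s / %s).",
      nrow(bad), bad$participant_id[1], bad$food_id[1]
    ))
  }
  judgments |>
    dplyr::group_by(.data$participant_id, .data$food_id) |>
    dplyr::group_modify(function(j, key) {
      props <- j |>
        dplyr::summarise(prop = mean(.data$response), reps = dplyr::n(),
                         .by = "size")
      majority_range(props$size, props$prop >= threshold - 1e-9,
                     n_basis = props$reps[1],
                     label = paste(key$participant_id, key$food_id))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(scope = "individual", .before = 1)
}

# Shared min/max-of-qualifying-sizes rule with non-contiguity warning.
majority_range <- function(sizes, qualifies, n_basis, label) {
  ord <- order(sizes)
  sizes <- sizes[ord]
  qualifies <- qualifies[ord]
  if (!any(qualifies)) {
    return(tibble::tibble(lower = NA_real_, upper = NA_real_,
                          valid = FALSE, n_basis = n_basis))
  }
  lower <- min(sizes[qualifies])
  upper <- max(sizes[qualifies])
  interior <- sizes > lower & sizes < upper
  dips <- sizes[interior & !qualifies]
  if (length(dips) > 0) {
    rlang::warn(sprintf(
      "Non-contiguous majority region for %s: interior size(s) %s fall below the criterion; range kept as [%g, %g].",
      label, paste(dips, collapse = ", "), lower, upper
    ))
  }
  tibble::tibble(lower = lower, upper = upper, valid = TRUE, n_basis = n_basis)
}

check_threshold <- function(threshold) {
  if (length(threshold) != 1 || threshold <= 0.5 || threshold > 1) {
    rlang::abort("`threshold` must be a single proportion in (0.5, 1].")
  }
}

check_judgments <- function(judgments) {
  if (!is.data.frame(judgments) || nrow(judgments) == 0) {
    rlang::abort("`judgments` must be a non-empty data frame.")
  }
  need <- c("participant_id", "food_id", "size", "response")
  miss <- setdiff(need, names(judgments))
  if (length(miss) > 0) {
    rlang::abort(sprintf("`judgments` is missing column(s): %s.",
                         paste(miss, collapse = ", ")))
  }
  if (!all(judgments$response %in% c(0L, 1L))) {
    rlang::abort("`response` must be binary (0/1).")
  }
}

#' Classify portion sizes against a norm range
#'
#' A portion is `below` the norm range when smaller than the lower boundary,
#' `above` when larger than the upper boundary, and `within` otherwise;
#' boundary sizes count as within (printed ranges such as 80-160% are read
#' inclusively).
#'
#' @param size Portion size(s), percent of reference.
#' @param lower,upper Norm-range boundaries (recycled against `size`).
#' @return A factor with levels `below`, `within`, `above`.
#' @export
classify_portion <- function(size, lower, upper) {
  if (any(is.na(lower) | is.na(upper))) {
    rlang::abort("Cannot classify against an invalid (NA) norm range.")
  }
  factor(c("below", "within", "above")[portion_category_numeric(size, lower, upper)],
         levels = c("below", "within", "above"))
}

#' Classify size pairs by norm-range boundary position
#'
#' Pairs are `within` when both members lie inside the range, `across_lower`
#' / `across_upper` when they straddle one boundary, `outside_below` /
#' `outside_above` when both members fall on the same side outside the
#' range, and `spanning` when the small member is below and the large member
#' above the whole range. Only the first three categories enter the
#' boundary-sensitivity and discrimination analyses.
#'
#' @param small,large Pair member sizes, percent of reference.
#' @param lower,upper Norm-range boundaries.
#' @return A factor with levels `across_lower`, `within`, `across_upper`,
#'   `outside_below`, `outside_above`, `spanning`.
#' @export
classify_pair <- function(small, large, lower, upper) {
  if (any(is.na(lower) | is.na(upper))) {
    rlang::abort("Cannot classify against an invalid (NA) norm range.")
  }
  cs <- portion_category_numeric(small, lower, upper)
  cl <- portion_category_numeric(large, lower, upper)
  out <- dplyr::case_when(
    cs == 1 & cl == 1 ~ "outside_below",
    cs == 1 & cl == 2 ~ "across_lower",
    cs == 1 & cl == 3 ~ "spanning",
    cs == 2 & cl == 2 ~ "within",
    cs == 2 & cl == 3 ~ "across_upper",
    cs == 3 & cl == 3 ~ "outside_above"
  )
  factor(out, levels = c("across_lower", "within", "across_upper",
                         "outside_below", "outside_above", "spanning"))
}
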