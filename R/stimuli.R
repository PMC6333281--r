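#' Build a portion-size stimulus grid
#'
#' Constructs the ordered set of portion sizes shown for one food, expressed
#' in integer percent of the manufacturer's reference portion. The standard
#' design steps in 10% increments from 40% to 300% (27 sizes); an extended
#' grid runs to 400% (37 sizes) for foods whose reference portion is small
#' relative to typical servings.
#'
#' @param min_pct Smallest portion size, percent of reference.
#' @param max_pct Largest portion size, percent of reference.
#' @param step_pct Increment between consecutive sizes, percent. Default 10.
#' @param food_id Label attached to every row. Default `"food"`.
#'
#' @return A tibble with columns `food_id`, `size`, `step`, one row per
#'   portion size, sizes strictly increasing.
#'
#' @examples
#' build_grid(40, 300, 10, food_id = "pasta")   # 27 sizes
#' build_grid(40, 400, 10, food_id = "cake")    # 37 sizes
#' @export
build_grid <- function(min_pct, max_pct, step_pct = 10, food_id = "food") {
  stopifnot(length(min_pct) == 1, length(max_pct) == 1, length(step_pct) == 1)
  if (!is.numeric(step_pct) || step_pct <= 0) {
    rlang::abort("`step_pct` must be a positive number.")
  }
  if (min_pct > max_pct) {
    rlang::abort("`min_pct` must not exceed `max_pct`.")
  }
  if (min_pct < step_pct) {
    rlang::abort("`min_pct` must be at least one step (sizes must be >= step).")
  }
  span <- max_pct - min_pct
  if (abs(span / step_pct - round(span / step_pct)) > 1e-8) {
    rlang::abort(sprintf(
      "Range %s-%s is not divisible by step %s; refusing to truncate the grid.",
      min_pct, max_pct, step_pct
    ))
  }
  tibble::tibble(
    food_id = as.character(food_id),
    size = seq(min_pct, max_pct, by = step_pct),
    step = step_pct
  )
}

#' Build fixed-increment comparison pairs from a grid
#'
#' Enumerates every unordered pair of grid sizes separated by exactly
#' `delta_pct` percent of the reference portion. Pairs are the stimuli of the
#' relative size judgment task: both members of a pair differ by the same
#' absolute amount of food, so any change in discriminability across the grid
#' reflects Weber's law or category structure, not the physical increment.
#'
#' @param grid A stimulus grid tibble from [build_grid()]; may contain
#'   several foods.
#' @param delta_pct Size difference between pair members, percent of the
#'   reference portion; must be a positive multiple of the grid step.
#'   Default 20.
#'
#' @return A tibble with columns `food_id`, `small`, `large`, `delta`,
#'   ascending by `small` within food. A 27-size grid yields 25 pairs at
#'   `delta_pct = 20`.
#' @export
build_pairs <- function(grid, delta_pct = 20) {
  stopifnot(is.data.frame(grid), all(c("food_id", "size", "step") %in% names(grid)))
  if (length(delta_pct) != 1 || delta_pct <= 0) {
    rlang::abort("`delta_pct` must be a single positive number.")
  }
  grid |>
    dplyr::group_by(.data$food_id) |>
    dplyr::group_modify(function(g, key) {
      step <- g$step[1]
      if (abs(delta_pct / step - round(delta_pct / step)) > 1e-8) {
        rlang::abort(sprintf(
          "`delta_pct` (%s) must be a multiple of the grid step (%s).",
          delta_pct, step
        ))
      }
      small <- g$size[(g$size + delta_pct) %in% g$size]
      tibble::tibble(small = small, large = small + delta_pct, delta = delta_pct)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$food_id, .data$small)
}

#' Stimulus grids of the two-study portion-size design
#'
#' Convenience constructor for the published stimulus sets: four foods on the
#' 40-300% grid and chocolate cake on the extended 40-400% grid (study 1), or
#' the two main-meal foods (pasta, curry) on the 40-300% grid (study 2).
#'
#' @param study 1 or 2.
#' @return A grid tibble (see [build_grid()]).
#' @export
study_grids <- function(study = 1) {
  if (study == 1) {
    dplyr::bind_rows(
      build_grid(40, 300, 10, food_id = "porridge"),
      build_grid(40, 300, 10, food_id = "curry"),
      build_grid(40, 300, 10, food_id = "pasta"),
      build_grid(40, 300, 10, food_id = "crisps"),
      build_grid(40, 400, 10, food_id = "cake")
    )
  } else if (study == 2) {
    dplyr::bind_rows(
      build_grid(40, 300, 10, food_id = "pasta"),
      build_grid(40, 300, 10, food_id = "curry")
    )
  } else {
    rlang::abort("`study` must be 1 or 2.")
  }
}
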