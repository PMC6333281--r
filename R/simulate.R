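#' Sample a panel of simulated participants
#'
#' Draws each participant's true lower and upper normality boundary from
#' independent normals (`mu_L`, `sigma_L`; `mu_U`, `sigma_U`), redrawing any
#' participant whose lower boundary lands at or above their upper boundary.
#' The relative size judgment instruction ("which is larger" vs "which is
#' smaller") alternates deterministically by participant index, emulating
#' counterbalancing.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `participant_id`, `true_L`, `true_U`,
#'   `judgment_type`.
#' @export
sample_participants <- function(config) {
  validate_cohort_config(config)
  if (config$sigma_L == 0 && config$sigma_U == 0 && config$mu_L >= config$mu_U) {
    rlang::abort("Degenerate config: zero-variance boundaries with mu_L >= mu_U.")
  }
  n <- config$n_participants
  set.seed(stage_seed(config$seed, "participants"))
  true_L <- stats::rnorm(n, config$mu_L, config$sigma_L)
  true_U <- stats::rnorm(n, config$mu_U, config$sigma_U)
  bad <- which(true_L >= true_U)
  while (length(bad) > 0) {
    true_L[bad] <- stats::rnorm(length(bad), config$mu_L, config$sigma_L)
    true_U[bad] <- stats::rnorm(length(bad), config$mu_U, config$sigma_U)
    bad <- bad[true_L[bad] >= true_U[bad]]
  }
  tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    true_L = true_L,
    true_U = true_U,
    judgment_type = ifelse(seq_len(n) %% 2 == 1, "larger", "smaller")
  )
}

#' Probability of judging a portion size "normal"
#'
#' The generative response model: a soft two-boundary category. For positive
#' fuzziness the probability is the product of two logistic edges,
#' `plogis((s - L)/k_L) * plogis((U - s)/k_U)`; at `k = 0` it collapses to
#' the hard indicator of `L <= s <= U`.
#'
#' @param size Portion size(s), percent of reference.
#' @param true_L,true_U The participant's true boundaries.
#' @param k_L,k_U Fuzziness of the lower/upper boundary (percent); `0` means
#'   a hard edge.
#' @return Probabilities, vectorised over `size` (and the boundaries).
#' @export
p_normal <- function(size, true_L, true_U, k_L = 0, k_U = 0) {
  stopifnot(k_L >= 0, k_U >= 0)
  lower <- if (k_L == 0) as.numeric(size >= true_L) else
    stats::plogis((size - true_L) / k_L)
  upper <- if (k_U == 0) as.numeric(size <= true_U) else
    stats::plogis((true_U - size) / k_U)
  lower * upper
}

#' Simulate the normality judgment table
#'
#' One Bernoulli draw from [p_normal()] per participant x food x size x
#' repetition.
#'
#' @param panel Participant tibble from [sample_participants()].
#' @param grid Stimulus grid from [build_grid()] / [study_grids()].
#' @param config A [cohort_config()].
#' @return Tibble with columns `participant_id`, `food_id`, `size`, `rep`,
#'   `response` (1 = judged normal).
#' @export
simulate_normality_judgments <- function(panel, grid, config) {
  validate_cohort_config(config)
  set.seed(stage_seed(config$seed, "normality"))
  out <- tidyr::expand_grid(
    panel[c("participant_id", "true_L", "true_U")],
    grid[c("food_id", "size")],
    rep = seq_len(config$n_norm_reps)
  )
  p <- p_normal(out$size, out$true_L, out$true_U, config$k_L, config$k_U)
  out$response <- ifelse(p %in% c(0, 1), p, NA_real_)
  stoch <- is.na(out$response)
  out$response[stoch] <- stats::rbinom(sum(stoch), 1L, p[stoch])
  out$response <- as.integer(out$response)
  dplyr::select(out, "participant_id", "food_id", "size", "rep", "response") |>
    dplyr::arrange(.data$participant_id, .data$food_id, .data$size, .data$rep)
}

#' Latent intended consumption for a portion size
#'
#' The piecewise-linear latent intention model. Within the participant's true
#' norm range the latent value is `4 + beta_within * (c - s) / 100` with `c`
#' the range centre, so the centre is anchored exactly at the Likert midpoint
#' (eat the whole portion, no more). Below the lower boundary the steeper
#' `beta_below` slope takes over continuously (compensatory eating: whole
#' portion plus more); above the upper boundary `beta_above` pulls intent
#' down (eat only part). Slopes are in Likert units per 100 percent-points
#' and the function is continuous at both knots.
#'
#' @param size Portion size(s), percent of reference.
#' @param true_L,true_U True boundaries (vectorised with `size`).
#' @param config A [cohort_config()] supplying the three slopes.
#' @return Latent intention values (unbounded reals).
#' @export
latent_intention <- function(size, true_L, true_U, config) {
  centre <- (true_L + true_U) / 2
  at_L <- 4 + config$beta_within * (centre - true_L) / 100
  at_U <- 4 + config$beta_within * (centre - true_U) / 100
  dplyr::case_when(
    size < true_L ~ at_L + config$beta_below * (true_L - size) / 100,
    size > true_U ~ at_U - config$beta_above * (size - true_U) / 100,
    .default = 4 + config$beta_within * (centre - size) / 100
  )
}

#' Simulate the intended consumption table
#'
#' One 1-7 rating per participant x food x size: latent intention plus
#' Gaussian noise, rounded to the nearest scale point and clamped to the
#' scale ends.
#'
#' @inheritParams simulate_normality_judgments
#' @return Tibble with columns `participant_id`, `food_id`, `size`, `rating`.
#' @export
simulate_intention_ratings <- function(panel, grid, config) {
  validate_cohort_config(config)
  set.seed(stage_seed(config$seed, "intention"))
  out <- tidyr::expand_grid(
    panel[c("participant_id", "true_L", "true_U")],
    grid[c("food_id", "size")]
  )
  latent <- latent_intention(out$size, out$true_L, out$true_U, config)
  noisy <- latent + stats::rnorm(nrow(out), 0, config$sigma_int)
  out$rating <- as.integer(pmin(pmax(round(noisy), 1), 7))
  dplyr::select(out, "participant_id", "food_id", "size", "rating") |>
    dplyr::arrange(.data$participant_id, .data$food_id, .data$size)
}

#' Simulate the relative size judgment table
#'
#' Discriminability of a pair is `d = delta / (weber_w * mean_size)` (Weber's
#' law) plus `cat_boost_b` when the two members fall in different perceptual
#' categories of the participant's true norm range (categorical perception:
#' any category change sharpens discrimination, including pairs spanning a
#' very narrow range). Accuracy follows `plogis(acc_scale_a * d)` so chance
#' is 0.5 at `d = 0`; RT is shifted-lognormal decreasing in `d`. A small
#' fraction of trials is contaminated: anticipatory responses (RT replaced by
#' Uniform(100, 349) ms) and lapses (RT multiplied by 10), which exist to
#' exercise the trimming stage. The side carrying the larger portion
#' alternates across repetitions so it is balanced within pair.
#'
#' @param panel Participant tibble from [sample_participants()].
#' @param pairs Pair tibble from [build_pairs()].
#' @param config A [cohort_config()].
#' @return Tibble with columns `participant_id`, `food_id`, `small`, `large`,
#'   `rep`, `larger_side`, `response_side`, `correct`, `rt_ms`.
#' @export
simulate_discrimination <- function(panel, pairs, config) {
  validate_cohort_config(config)
  set.seed(stage_seed(config$seed, "discrimination"))
  out <- tidyr::expand_grid(
    panel[c("participant_id", "true_L", "true_U", "judgment_type")],
    pairs[c("food_id", "small", "large", "delta")],
    rep = seq_len(config$n_pair_reps)
  )
  mid <- (out$small + out$large) / 2
  cat_small <- portion_category_numeric(out$small, out$true_L, out$true_U)
  cat_large <- portion_category_numeric(out$large, out$true_L, out$true_U)
  crossed <- cat_small != cat_large
  d <- out$delta / (config$weber_w * mid) + config$cat_boost_b * crossed
  out$correct <- stats::rbinom(nrow(out), 1L, stats::plogis(config$acc_scale_a * d))

  rt <- config$t0_ms +
    exp(config$mu_rt - config$gamma_rt * d + stats::rnorm(nrow(out), 0, config$sigma_rt))
  contam <- stats::runif(nrow(out))
  anticipatory <- contam < config$p_anticipatory
  outlier <- !anticipatory & contam < config$p_anticipatory + config$p_outlier
  rt[anticipatory] <- stats::runif(sum(anticipatory), 100, 349)
  rt[outlier] <- rt[outlier] * 10
  out$rt_ms <- rt

  out$larger_side <- ifelse(out$rep %% 2 == 1, "left", "right")
  queried <- ifelse(out$judgment_type == "larger",
                    out$larger_side,
                    ifelse(out$larger_side == "left", "right", "left"))
  out$response_side <- ifelse(out$correct == 1L, queried,
                              ifelse(queried == "left", "right", "left"))
  dplyr::select(out, "participant_id", "food_id", "small", "large", "rep",
                "larger_side", "response_side", "correct", "rt_ms") |>
    dplyr::arrange(.data$participant_id, .data$food_id, .data$small, .data$rep)
}

# 1/2/3 coding of below/within/above relative to a (possibly real-valued)
# boundary pair; boundaries inclusive.
portion_category_numeric <- function(size, lower, upper) {
  ifelse(size < lower, 1L, ifelse(size > upper, 3L, 2L))
}

#' Simulate a full cohort: panel plus all three trial tables
#'
#' Convenience wrapper running [sample_participants()],
#' [simulate_normality_judgments()], [simulate_intention_ratings()] and
#' [simulate_discrimination()] on a common stimulus design. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param grid Stimulus grid; defaults to the two-food main-meal design
#'   ([study_grids()] with `study = 2`).
#' @param delta_pct Pair increment, percent. Default 20.
#' @return A list with elements `panel`, `normality`, `intention`,
#'   `sizejudgment`, `grid`, `pairs`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), grid = study_grids(2),
                            delta_pct = 20) {
  panel <- sample_participants(config)
  pairs <- build_pairs(grid, delta_pct)
  list(
    panel = panel,
    normality = simulate_normality_judgments(panel, grid, config),
    intention = simulate_intention_ratings(panel, grid, config),
    sizejudgment = simulate_discrimination(panel, pairs, config),
    grid = grid,
    pairs = pairs,
    config = config
  )
}
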