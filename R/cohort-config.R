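#' Configuration for the synthetic cohort generator
#'
#' Collects every parameter of the generative model behind the synthetic
#' cohort: a two-boundary categorical-perception model of normality
#' judgments, a piecewise-linear latent intention model anchored at the
#' Likert midpoint, and a Weber-law discrimination model with an optional
#' categorical boost, plus a shifted-lognormal reaction-time model with
#' anticipatory/outlier contamination.
#'
#' Defaults describe the cohort the package's recovery analyses simulate:
#' 40 participants whose lower/upper normality boundaries are drawn around
#' 85% and 160% of the reference portion (giving collective norm ranges in
#' the neighbourhood of the published 70-190% spans), steep intention slopes
#' outside the norm range (4 Likert units per 100 percent-points) against a
#' shallow slope inside (1), rating noise of 0.6 Likert units, a Weber
#' fraction of 0.15 with accuracy scale 1.5, and roughly 2% contaminated
#' reaction times.
#'
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed governing every stochastic stage.
#' @param mu_L,sigma_L Mean and SD (percent of reference) of the true lower
#'   normality boundary across participants.
#' @param mu_U,sigma_U Mean and SD of the true upper boundary.
#' @param k_L,k_U Boundary fuzziness (percent). `0` makes judgments a hard
#'   indicator of the true range; larger values give logistic response noise
#'   near each boundary.
#' @param beta_below,beta_within,beta_above Intention slopes, Likert units
#'   per 100 percent-points, for sizes below, inside, and above the norm
#'   range. Steeper outer slopes produce the compensatory-eating /
#'   leave-some-behind pattern.
#' @param sigma_int SD of rating noise, Likert units.
#' @param weber_w Weber fraction: discriminability of a pair is
#'   `delta / (weber_w * mean_size)`.
#' @param cat_boost_b Discriminability increment added when the two pair
#'   members fall in different perceptual categories of the participant's
#'   true norm range.
#' @param acc_scale_a Accuracy link scale: P(correct) =
#'   `plogis(acc_scale_a * d)`, chance 0.5 at `d = 0`.
#' @param t0_ms,mu_rt,gamma_rt,sigma_rt Shifted-lognormal RT model:
#'   `t0_ms + exp(mu_rt - gamma_rt * d + Normal(0, sigma_rt))` milliseconds.
#' @param p_anticipatory Probability a trial's RT is replaced by an
#'   anticipatory response, Uniform(100, 349) ms.
#' @param p_outlier Probability a trial's RT is multiplied by 10 (lapse).
#' @param n_norm_reps Repetitions of each normality judgment (1 emulates
#'   the single-judgment study, 10 the repeated-judgment study).
#' @param n_pair_reps Repetitions of each relative size judgment pair.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_participants = 40,
                          seed = 1L,
                          mu_L = 85, sigma_L = 12,
                          mu_U = 160, sigma_U = 18,
                          k_L = 5, k_U = 5,
                          beta_below = 4, beta_within = 1, beta_above = 4,
                          sigma_int = 0.6,
                          weber_w = 0.15,
                          cat_boost_b = 0.5,
                          acc_scale_a = 1.5,
                          t0_ms = 300, mu_rt = 8.2, gamma_rt = 0.25,
                          sigma_rt = 0.4,
                          p_anticipatory = 0.01, p_outlier = 0.01,
                          n_norm_reps = 10, n_pair_reps = 10) {
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    mu_L = mu_L, sigma_L = sigma_L, mu_U = mu_U, sigma_U = sigma_U,
    k_L = k_L, k_U = k_U,
    beta_below = beta_below, beta_within = beta_within,
    beta_above = beta_above, sigma_int = sigma_int,
    weber_w = weber_w, cat_boost_b = cat_boost_b, acc_scale_a = acc_scale_a,
    t0_ms = t0_ms, mu_rt = mu_rt, gamma_rt = gamma_rt, sigma_rt = sigma_rt,
    p_anticipatory = p_anticipatory, p_outlier = p_outlier,
    n_norm_reps = as.integer(n_norm_reps), n_pair_reps = as.integer(n_pair_reps)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) rlang::abort("`n_participants` must be >= 1.")
  if (cfg$mu_L >= cfg$mu_U) {
    rlang::abort("Boundary means must satisfy `mu_L < mu_U`.")
  }
  sds <- c(sigma_L = cfg$sigma_L, sigma_U = cfg$sigma_U,
           sigma_int = cfg$sigma_int, sigma_rt = cfg$sigma_rt,
           k_L = cfg$k_L, k_U = cfg$k_U)
  if (any(sds < 0)) {
    rlang::abort(sprintf("Negative scale parameter: %s.",
                         paste(names(sds)[sds < 0], collapse = ", ")))
  }
  if (cfg$weber_w <= 0) rlang::abort("`weber_w` must be > 0.")
  ps <- c(cfg$p_anticipatory, cfg$p_outlier)
  if (any(ps < 0 | ps > 1)) {
    rlang::abort("Contamination probabilities must lie in [0, 1].")
  }
  if (cfg$n_norm_reps < 1 || cfg$n_pair_reps < 1) {
    rlang::abort("Repetition counts must be >= 1.")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d participants, seed %d\n", x$n_participants, x$seed))
  cat(sprintf("  boundaries: L ~ N(%g, %g), U ~ N(%g, %g), fuzz k = (%g, %g)\n",
              x$mu_L, x$sigma_L, x$mu_U, x$sigma_U, x$k_L, x$k_U))
  cat(sprintf("  intention slopes (below/within/above): %g / %g / %g, sigma %g\n",
              x$beta_below, x$beta_within, x$beta_above, x$sigma_int))
  cat(sprintf("  discrimination: w = %g, boost = %g, scale = %g\n",
              x$weber_w, x$cat_boost_b, x$acc_scale_a))
  cat(sprintf("  RT: t0 %g ms, mu %g, gamma %g, sigma %g; contamination %g/%g\n",
              x$t0_ms, x$mu_rt, x$gamma_rt, x$sigma_rt,
              x$p_anticipatory, x$p_outlier))
  cat(sprintf("  reps: %d normality, %d pair\n", x$n_norm_reps, x$n_pair_reps))
  invisible(x)
}

# Deterministic per-stage seed derived from the config seed, kept in 32-bit
# integer range so set.seed() accepts it.
stage_seed <- function(seed, stage) {
  offset <- c(participants = 11L, normality = 29L, intention = 47L,
              discrimination = 83L)[[stage]]
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}
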