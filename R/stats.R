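#' One-sample t-test with degenerate-case handling
#'
#' A thin wrapper around [stats::t.test()] that returns a tidy one-row
#' result and never throws on zero-variance input: all values equal to `mu0`
#' yields `t = 0, p = 1`; all values equal but different from `mu0` yields an
#' infinite statistic with `p = 0`, flagged `degenerate`, so simulation
#' sweeps over many cells never crash.
#'
#' @param values Numeric vector, length >= 2.
#' @param mu0 Null value. Default 4 (the Likert midpoint: eat the whole
#'   portion, no more).
#' @param alpha_adjusted Significance threshold recorded alongside the test
#'   (e.g. a Bonferroni-corrected level). Default 0.05.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_difference`,
#'   `se`, `alpha_adjusted`, `significant`, `degenerate`.
#' @export
one_sample_t <- function(values, mu0 = 4, alpha_adjusted = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) rlang::abort("Need at least 2 non-missing values.")
  md <- mean(values) - mu0
  s <- stats::sd(values)
  if (essentially_constant(values, s)) {
    stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    return(t_result(stat, n - 1, p, md, 0, alpha_adjusted, degenerate = md != 0))
  }
  ht <- stats::t.test(values, mu = mu0)
  t_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
           md, s / sqrt(n), alpha_adjusted, degenerate = FALSE)
}

# t.test()'s own refusal criterion: a spread at rounding-noise level relative
# to the values' magnitude counts as zero variance.
essentially_constant <- function(values, s) {
  s == 0 || s < 10 * .Machine$double.eps * max(abs(values), 1)
}

t_result <- function(stat, df, p, md, se, alpha_adjusted, degenerate) {
  tibble::tibble(
    statistic = stat, df = df, p_value = p,
    mean_difference = md, se = se,
    alpha_adjusted = alpha_adjusted,
    significant = p < alpha_adjusted,
    degenerate = degenerate
  )
}

#' Paired within-subject comparison of two factor levels
#'
#' Averages the dependent variable to one value per subject and level, then
#' runs a paired t-test of level `i` minus level `j`. Reports the mean
#' difference and its standard error. A zero-variance difference is flagged
#' degenerate rather than raising.
#'
#' @param data Long data frame.
#' @param dv,subject,factor Column names (strings) of the response, the
#'   subject identifier, and the within-subject factor.
#' @param levels Length-2 character vector: the two factor levels to
#'   compare, difference taken as first minus second.
#' @param alpha_adjusted Significance threshold recorded with the result.
#' @return One-row tibble as [one_sample_t()], plus `level_1`, `level_2`,
#'   `n`.
#' @export
pairwise_within <- function(data, dv, subject, factor, levels,
                            alpha_adjusted = 0.05) {
  stopifnot(length(levels) == 2)
  cell <- data |>
    dplyr::filter(.data[[factor]] %in% levels) |>
    dplyr::summarise(.value = mean(.data[[dv]]),
                     .by = dplyr::all_of(c(subject, factor))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(factor),
                       values_from = ".value") |>
    dplyr::filter(!is.na(.data[[levels[1]]]), !is.na(.data[[levels[2]]]))
  n <- nrow(cell)
  if (n < 2) {
    rlang::abort(sprintf("Need >= 2 complete pairs for %s vs %s (got %d).",
                         levels[1], levels[2], n))
  }
  d <- cell[[levels[1]]] - cell[[levels[2]]]
  md <- mean(d)
  s <- stats::sd(d)
  res <- if (essentially_constant(d, s)) {
    stat <- if (md == 0) 0 else sign(md) * Inf
    t_result(stat, n - 1, if (md == 0) 1 else 0, md, 0, alpha_adjusted,
             degenerate = md != 0)
  } else {
    ht <- stats::t.test(d, mu = 0)
    t_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
             md, s / sqrt(n), alpha_adjusted, degenerate = FALSE)
  }
  dplyr::mutate(res, level_1 = levels[1], level_2 = levels[2], n = n,
                .before = 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Familywise error rate. Default 0.05.
#' @param k Number of comparisons in the family.
#' @return One-row tibble: `alpha`, `k`, `alpha_adjusted` (full precision),
#'   `display` (rounded to three decimals in the conventional print style,
#'   e.g. `".003"` for `0.05 / 15`).
#' @export
bonferroni_alpha <- function(alpha = 0.05, k) {
  if (length(k) != 1 || k < 1) rlang::abort("`k` must be a count >= 1.")
  adj <- alpha / k
  tibble::tibble(
    alpha = alpha, k = as.integer(k), alpha_adjusted = adj,
    display = sub("^0", "", sprintf("%.3f", adj))
  )
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One- or two-way fully within-subjects ANOVA on a complete balanced design
#' with one observation per subject x cell (aggregate first if needed). For
#' each effect it reports the F ratio against that effect's own
#' subject-interaction error term, partial eta-squared
#' (`SS_effect / (SS_effect + SS_error)`), the Greenhouse-Geisser epsilon
#' estimated from the orthonormalised contrast covariance, and both the
#' uncorrected and the epsilon-corrected p-value. Epsilon is exactly 1 for
#' two-level factors.
#'
#' @param data Long data frame, one row per subject x cell.
#' @param dv Response column name (string).
#' @param subject Subject identifier column name.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param correction Apply the Greenhouse-Geisser df correction when
#'   computing `p_value`? Default `TRUE` (the uncorrected p is always
#'   reported as `p_uncorrected`).
#' @return An object of class `nr_anova`: a list with `table` (one row per
#'   effect: `effect`, `df_num`, `df_den`, `ss_effect`, `ss_error`,
#'   `statistic`, `epsilon_gg`, `p_uncorrected`, `p_value`,
#'   `partial_eta_sq`), `n_subjects`, `within`, `correction`.
#' @export
rm_anova <- function(data, dv, subject, within, correction = TRUE) {
  stopifnot(length(within) %in% 1:2)
  cols <- c(dv, subject, within)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    rlang::abort(sprintf("Missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  data <- dplyr::as_tibble(data)[cols]
  if (anyNA(data[[dv]])) rlang::abort("Response contains missing values.")

  subj <- factor(data[[subject]])
  fA <- factor(data[[within[1]]])
  fB <- if (length(within) == 2) factor(data[[within[2]]]) else
    factor(rep("1", nrow(data)))
  a <- nlevels(fA); b <- nlevels(fB); n <- nlevels(subj)
  if (n < 2) rlang::abort("Repeated-measures ANOVA needs >= 2 subjects.")

  counts <- table(subj, fA, fB)
  if (any(counts != 1)) {
    rlang::abort(paste0(
      "Design must be complete with exactly one observation per subject x cell; ",
      sum(counts == 0), " empty and ", sum(counts > 1),
      " duplicated cell(s) found. Aggregate or filter to complete subjects first."
    ))
  }

  y <- data[[dv]]
  # subject x cell matrix, cells ordered A-major then B
  Y <- matrix(NA_real_, n, a * b)
  cell_idx <- (as.integer(fA) - 1L) * b + as.integer(fB)
  Y[cbind(as.integer(subj), cell_idx)] <- y

  gm <- mean(Y)
  m_s <- rowMeans(Y)
  m_A <- vapply(seq_len(a), function(i) mean(Y[, ((i - 1) * b + 1):(i * b)]),
                numeric(1))
  m_B <- vapply(seq_len(b), function(j) mean(Y[, seq(j, a * b, by = b)]),
                numeric(1))
  m_AB <- matrix(colMeans(Y), a, b, byrow = TRUE)
  m_sA <- vapply(seq_len(a), function(i)
    rowMeans(Y[, ((i - 1) * b + 1):(i * b), drop = FALSE]), numeric(n))
  m_sB <- vapply(seq_len(b), function(j)
    rowMeans(Y[, seq(j, a * b, by = b), drop = FALSE]), numeric(n))

  eff <- list()
  ss_A <- n * b * sum((m_A - gm)^2)
  ss_AS <- b * sum((m_sA - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_A) + gm)^2)
  eff[[within[1]]] <- list(ss = ss_A, df = a - 1, ss_e = ss_AS,
                           df_e = (a - 1) * (n - 1),
                           eps = gg_epsilon(m_sA))
  if (b > 1) {
    ss_B <- n * a * sum((m_B - gm)^2)
    ss_BS <- a * sum((m_sB - outer(m_s, rep(1, b)) -
                        outer(rep(1, n), m_B) + gm)^2)
    eff[[within[2]]] <- list(ss = ss_B, df = b - 1, ss_e = ss_BS,
                             df_e = (b - 1) * (n - 1),
                             eps = gg_epsilon(m_sB))
    ss_AB <- n * sum((m_AB - outer(m_A, rep(1, b)) -
                        outer(rep(1, a), m_B) + gm)^2)
    resid <- Y
    for (i in seq_len(a)) for (j in seq_len(b)) {
      col <- (i - 1) * b + j
      resid[, col] <- Y[, col] - m_sA[, i] - m_sB[, j] - m_AB[i, j] +
        m_s + m_A[i] + m_B[j] - gm
    }
    eff[[paste(within, collapse = ":")]] <- list(
      ss = ss_AB, df = (a - 1) * (b - 1), ss_e = sum(resid^2),
      df_e = (a - 1) * (b - 1) * (n - 1),
      eps = gg_epsilon_interaction(Y, a, b)
    )
  }

  table <- purrr::imap(eff, function(e, name) {
    # zero effect SS gives F = 0 even when the error SS is also zero
    f <- if (e$ss == 0) 0 else (e$ss / e$df) / (e$ss_e / e$df_e)
    p_unc <- stats::pf(f, e$df, e$df_e, lower.tail = FALSE)
    p_gg <- stats::pf(f, e$df * e$eps, e$df_e * e$eps, lower.tail = FALSE)
    tibble::tibble(
      effect = name, df_num = e$df, df_den = e$df_e,
      ss_effect = e$ss, ss_error = e$ss_e,
      statistic = f, epsilon_gg = e$eps,
      p_uncorrected = p_unc,
      p_value = if (correction) p_gg else p_unc,
      partial_eta_sq = if (e$ss + e$ss_e == 0) 0 else e$ss / (e$ss + e$ss_e)
    )
  }) |> purrr::list_rbind()

  structure(list(table = table, n_subjects = n, within = within,
                 correction = correction),
            class = "nr_anova")
}

# Greenhouse-Geisser epsilon from the subject x level matrix of an effect:
# project onto orthonormal contrasts, epsilon = (tr S)^2 / (q tr S^2).
gg_epsilon <- function(M) {
  k <- ncol(M)
  if (k <= 2) return(1)
  C <- orthonormal_contrasts(k)
  S <- C %*% stats::cov(M) %*% t(C)
  if (sum(diag(S)) == 0) return(1)
  (sum(diag(S)))^2 / ((k - 1) * sum(S^2))
}

gg_epsilon_interaction <- function(Y, a, b) {
  if (a <= 2 && b <= 2) return(1)
  C <- kronecker(orthonormal_contrasts(a), orthonormal_contrasts(b))
  S <- C %*% stats::cov(Y) %*% t(C)
  if (sum(diag(S)) == 0) return(1)
  q <- (a - 1) * (b - 1)
  (sum(diag(S)))^2 / (q * sum(S^2))
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  t(C) / sqrt(colSums(C^2))
}

#' @export
print.nr_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects, %s correction)\n",
              x$n_subjects,
              if (x$correction) "Greenhouse-Geisser" else "no sphericity"))
  print(dplyr::mutate(
    x$table,
    dplyr::across(c("ss_effect", "ss_error", "statistic", "epsilon_gg",
                    "partial_eta_sq"), ~ round(.x, 3)),
    dplyr::across(c("p_uncorrected", "p_value"), ~ signif(.x, 3))
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname rm_anova
#' @param x An `nr_anova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nr_anova <- function(x, ...) x$table

#' @rdname rm_anova
#' @exportS3Method generics::glance
glance.nr_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_effects = nrow(x$table),
                 correction = x$correction)
}
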