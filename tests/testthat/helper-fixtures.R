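# Shared fixtures and independent brute-force oracles. Every oracle here is
# deliberately naive (loops, full enumeration) so it cannot share a bug with
# the vectorised implementation it checks.

# Enumerate all pairs of grid members exactly `delta` apart by double loop.
brute_force_pairs <- function(sizes, delta) {
  out <- list()
  for (i in seq_along(sizes)) {
    for (j in seq_along(sizes)) {
      if (sizes[j] - sizes[i] == delta) {
        out[[length(out) + 1]] <- c(small = sizes[i], large = sizes[j])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(small = numeric(0), large = numeric(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# Scan the grid with the hard indicator of [true_L, true_U]: smallest and
# largest grid points inside, or NULL when none.
brute_force_range <- function(sizes, true_L, true_U) {
  inside <- sizes[sizes >= true_L & sizes <= true_U]
  if (length(inside) == 0) return(NULL)
  c(lower = min(inside), upper = max(inside))
}

# Trial-by-trial re-implementation of the two-stage RT trim.
brute_force_trim <- function(rt, floor_ms, k_sd) {
  keep1 <- rt >= floor_ms
  kept <- rt[keep1]
  thr <- mean(kept) + k_sd * sd(kept)
  keep2 <- keep1 & rt <= thr
  list(keep = keep2, threshold = thr)
}

# Normality table in which participants listed in `voters[[size]]` judge that
# size normal and everyone else does not (single judgment per size).
votes_table <- function(n_participants, sizes, votes_per_size,
                        food_id = "food") {
  rows <- list()
  for (k in seq_along(sizes)) {
    v <- votes_per_size[k]
    rows[[k]] <- data.frame(
      participant_id = sprintf("p%03d", seq_len(n_participants)),
      food_id = food_id,
      size = sizes[k],
      rep = 1L,
      response = as.integer(seq_len(n_participants) <= v)
    )
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# A small complete two-way within-subjects data set with known structure.
rm_fixture <- function(n = 6, a = 3, b = 2, seed = 101, effect_a = 0.5) {
  set.seed(seed)
  dat <- expand.grid(
    subject = sprintf("s%02d", seq_len(n)),
    A = paste0("a", seq_len(a)),
    B = paste0("b", seq_len(b)),
    stringsAsFactors = FALSE
  )
  intercepts <- rnorm(n)
  names(intercepts) <- sprintf("s%02d", seq_len(n))
  dat$y <- intercepts[dat$subject] +
    effect_a * as.integer(factor(dat$A)) + rnorm(nrow(dat), 0, 0.8)
  tibble::as_tibble(dat)
}

# car::Anova univariate RM-ANOVA on the same fixture, as independent oracle.
car_rm_anova <- function(data, dv, subject, within) {
  wide <- tidyr::pivot_wider(
    data,
    id_cols = dplyr::all_of(subject),
    names_from = dplyr::all_of(within),
    values_from = dplyr::all_of(dv),
    names_sort = TRUE
  )
  Y <- as.matrix(wide[-1])
  lv <- lapply(within, function(w) sort(unique(data[[w]])))
  idata <- rev(expand.grid(rev(lv), stringsAsFactors = TRUE))
  names(idata) <- within
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(stats::lm(Y ~ 1), idata = idata, idesign = idesign,
                   type = 3)
  summary(av, multivariate = FALSE)
}
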