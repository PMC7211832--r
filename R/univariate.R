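#' Per-bat roost-use summaries
#'
#' For each bat: the number of distinct roosts used, the number of roost
#' visits (capture events), the roost-switching rate (roosts used / visits),
#' and the mean pairwise distance between the distinct roosts used (metres;
#' 0 for single-roost bats, `NA` when coordinates are missing). Callers
#' normally filter to bats captured at least four times first, since the
#' switch rate is meaningless for rarely seen bats.
#'
#' @param ds A `capture_dataset`.
#' @param roosts Roost registry (defaults to `ds$roosts`).
#' @return A tibble with one row per bat: `bat_id`, `sex`, `population`,
#'   `n_roosts_used`, `n_visits`, `switch_rate`, `mean_roost_distance_m`.
#' @export
roost_use_summaries <- function(ds, roosts = ds$roosts) {
  stopifnot(inherits(ds, "capture_dataset"))
  dmat <- if (!is.null(roosts)) roost_distances(roosts) else NULL
  ds$captures |>
    dplyr::group_by(.data$bat_id) |>
    dplyr::summarise(
      sex = .data$sex[1],
      population = .data$population[1],
      n_roosts_used = dplyr::n_distinct(.data$roost_id),
      n_visits = dplyr::n_distinct(.data$event_id),
      roosts_used = list(unique(.data$roost_id)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      switch_rate = .data$n_roosts_used / .data$n_visits,
      mean_roost_distance_m = purrr::map_dbl(.data$roosts_used, function(rs) {
        if (length(rs) < 2) return(0)
        if (is.null(dmat) || !all(rs %in% rownames(dmat))) return(NA_real_)
        sub <- dmat[rs, rs]
        mean(sub[lower.tri(sub)])
      })
    ) |>
    dplyr::select(-"roosts_used")
}

# Shared machinery for two-group permutation tests. `statistic` maps
# (values_group1, values_group2) to a scalar; groups are taken in the factor
# level order of `labels`.
permuted_two_group_test <- function(values, labels, statistic, statistic_name,
                                    n_perm, seed, exact, min_group = 1) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(f) != 2) stop("labels must define exactly two groups", call. = FALSE)
  g1 <- values[f == levels(f)[1]]
  g2 <- values[f == levels(f)[2]]
  if (length(g1) < min_group || length(g2) < min_group) {
    stop(sprintf("each group needs at least %d value(s)", min_group), call. = FALSE)
  }
  obs <- statistic(g1, g2)
  n <- length(values)
  n1 <- length(g1)
  stat_for <- function(idx1) statistic(values[idx1], values[-idx1])

  if (exact) {
    splits <- combn(n, n1)
    nulls <- apply(splits, 2, stat_for)
    n_perm_used <- ncol(splits)
  } else {
    if (!is.null(seed)) set.seed(seed)
    nulls <- vapply(seq_len(n_perm), function(k) stat_for(sample.int(n, n1)),
                    numeric(1))
    n_perm_used <- n_perm
  }
  ep <- empirical_p(obs, nulls)
  structure(list(statistic = obs, statistic_name = statistic_name,
                 p_value = ep$p_value, p_display = ep$p_display,
                 groups = levels(f), n = c(length(g1), length(g2)),
                 n_perm = n_perm_used, exact = exact, nulls = nulls),
            class = "perm_test")
}

#' Permuted test of a difference in group means
#'
#' Statistic: `mean(group1) - mean(group2)` with the groups taken in factor
#' level order of `labels`. Significance comes from shuffling group labels
#' (`n_perm` random shuffles, or every split exactly when `exact = TRUE`),
#' with the two-sided-doubled convention of [empirical_p()].
#'
#' @param values Numeric vector of per-individual summaries.
#' @param labels Two-group labels (factor level order fixes orientation).
#' @param n_perm Number of random label shuffles (default 10000).
#' @param seed Optional integer seed.
#' @param exact Enumerate all label splits instead of sampling (feasible for
#'   small groups only).
#' @return A `perm_test` object (see [tidy.perm_test()]).
#' @export
permuted_mean_diff_test <- function(values, labels, n_perm = 10000, seed = NULL,
                                    exact = FALSE) {
  permuted_two_group_test(values, labels,
                          statistic = function(a, b) mean(a) - mean(b),
                          statistic_name = "mean_difference",
                          n_perm = n_perm, seed = seed, exact = exact,
                          min_group = 1)
}

#' Permuted test of a ratio of group variances
#'
#' Statistic: `var(group1) / var(group2)` with the groups in factor level
#' order (the report always states the orientation). A zero-variance
#' denominator gives an infinite statistic; the permutation p-value remains
#' defined. Both groups need at least two values.
#'
#' @inheritParams permuted_mean_diff_test
#' @param n_perm Number of random label shuffles (default 5000).
#' @return A `perm_test` object.
#' @export
permuted_variance_ratio_test <- function(values, labels, n_perm = 5000,
                                         seed = NULL, exact = FALSE) {
  permuted_two_group_test(values, labels,
                          statistic = function(a, b) {
                            v2 <- var(b)
                            if (v2 == 0) Inf else var(a) / v2
                          },
                          statistic_name = "variance_ratio",
                          n_perm = n_perm, seed = seed, exact = exact,
                          min_group = 2)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test: %s (%s - %s) = %.4g, p %s [%d %s]\n",
              x$statistic_name, x$groups[1], x$groups[2], x$statistic,
              x$p_display, x$n_perm,
              if (x$exact) "exhaustive splits" else "permutations"))
  invisible(x)
}

#' Tidy a permutation-test result
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return A one-row tibble: test name, group orientation, group sizes,
#'   statistic, p-value, permutation count.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    statistic_name = x$statistic_name,
    group_1 = x$groups[1], group_2 = x$groups[2],
    n_1 = x$n[1], n_2 = x$n[2],
    statistic = x$statistic,
    p_value = x$p_value, p_display = x$p_display,
    n_perm = x$n_perm, exact = x$exact
  )
}

#' Days between first juvenile capture and last adult capture
#'
#' Restricted to bats captured at least once as a juvenile and recaptured at
#' least once as an adult (on or after the first juvenile capture). Greater
#' variance of these spans in one sex is the capture-record signature of
#' philopatry in that sex.
#'
#' @param ds A `capture_dataset` (unfiltered: juveniles must be present).
#' @return A tibble: `bat_id`, `sex`, `span_days` (nonnegative).
#' @export
juvenile_recapture_spans <- function(ds) {
  stopifnot(inherits(ds, "capture_dataset"))
  ds$captures |>
    dplyr::group_by(.data$bat_id) |>
    dplyr::summarise(
      sex = .data$sex[1],
      first_juv = if (any(.data$age_class == "juvenile"))
        min(.data$date[.data$age_class == "juvenile"]) else as.Date(NA),
      last_adult = if (any(.data$age_class == "adult"))
        max(.data$date[.data$age_class == "adult"]) else as.Date(NA),
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$first_juv), !is.na(.data$last_adult),
                  .data$last_adult >= .data$first_juv) |>
    dplyr::mutate(span_days = as.integer(.data$last_adult - .data$first_juv)) |>
    dplyr::select("bat_id", "sex", "span_days")
}

#' Null distribution for the relatedness of co-roosting male pairs
#'
#' For every capture event containing exactly two reproductive (scrotal)
#' males, the observed statistic is the mean relatedness over those male
#' pairs. The null resamples, for each such event, two distinct adult males
#' from the pool captured in the same population and calendar year (or the
#' same roost and year, with `pool = "roost-year"`), averaging across events;
#' the 95% CI is the 2.5/97.5 percentile of the replicate means.
#'
#' @param ds A `capture_dataset`.
#' @param relatedness Symmetric relatedness matrix.
#' @param n_draws Number of null replicates (default 5000).
#' @param seed Optional integer seed.
#' @param pool `"population-year"` (default) or `"roost-year"`.
#' @return A list of class `two_male_null`: `observed_mean`, `ci` (length-2),
#'   `n_groups`, `n_draws`, `null_means`, `pool`.
#' @export
two_male_relatedness_null <- function(ds, relatedness, n_draws = 5000,
                                      seed = NULL,
                                      pool = c("population-year", "roost-year")) {
  pool <- match.arg(pool)
  stopifnot(inherits(ds, "capture_dataset"))
  adults_m <- ds$captures |> dplyr::filter(.data$sex == "male", .data$age_class == "adult")
  two_male_events <- adults_m |>
    dplyr::filter(!is.na(.data$repro_status), .data$repro_status == "scrotal") |>
    dplyr::group_by(.data$event_id) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(bat_a = .data$bat_id[1], bat_b = .data$bat_id[2],
                     population = .data$population[1], year = .data$year[1],
                     roost_id = .data$roost_id[1], .groups = "drop")
  if (nrow(two_male_events) == 0) {
    stop("no capture event contains exactly two reproductive males", call. = FALSE)
  }
  rel <- function(a, b) {
    if (a %in% rownames(relatedness) && b %in% rownames(relatedness))
      relatedness[a, b] else NA_real_
  }
  obs <- mean(mapply(rel, two_male_events$bat_a, two_male_events$bat_b), na.rm = TRUE)

  pools <- purrr::map(seq_len(nrow(two_male_events)), function(i) {
    ev <- two_male_events[i, ]
    p <- adults_m |> dplyr::filter(.data$population == ev$population,
                                   .data$year == ev$year)
    if (pool == "roost-year") p <- p |> dplyr::filter(.data$roost_id == ev$roost_id)
    unique(p$bat_id)
  })
  usable <- lengths(pools) >= 2
  if (!all(usable)) {
    warning(sum(!usable), " two-male group(s) skipped: fewer than 2 adult males in pool")
  }
  pools <- pools[usable]
  if (length(pools) == 0) stop("no two-male group has a usable male pool", call. = FALSE)

  if (!is.null(seed)) set.seed(seed)
  null_means <- vapply(seq_len(n_draws), function(k) {
    mean(vapply(pools, function(p) {
      pair <- sample(p, 2)
      rel(pair[1], pair[2])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  ci <- unname(quantile(null_means, c(0.025, 0.975), na.rm = TRUE))
  structure(list(observed_mean = obs, ci = ci,
                 n_groups = length(pools), n_draws = n_draws,
                 null_means = null_means, pool = pool),
            class = "two_male_null")
}

#' @export
print.two_male_null <- function(x, ...) {
  cat(sprintf(
    "Two-male relatedness: observed mean %.3f over %d groups; null 95%% CI %.3f-%.3f (%d draws, pool: %s)\n",
    x$observed_mean, x$n_groups, x$ci[1], x$ci[2], x$n_draws, x$pool))
  invisible(x)
}

#' @export
tidy.two_male_null <- function(x, ...) {
  tibble::tibble(observed_mean = x$observed_mean,
                 ci_lower = x$ci[1], ci_upper = x$ci[2],
                 n_groups = x$n_groups, n_draws = x$n_draws, pool = x$pool)
}
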