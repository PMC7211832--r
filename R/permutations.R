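#' Configuration for datastream (pre-network) permutations
#'
#' Null association networks are generated by repeatedly swapping pairs of
#' individual observations within the same population, roost and year, so that
#' every null network preserves each event's size, each bat's total sighting
#' count, and each bat's (population, roost, year) visit counts. The defaults
#' follow common datastream-permutation practice: 5000 sampled networks, 100
#' accepted swaps between successive samples, 1000 accepted burn-in swaps.
#'
#' @param n_networks Number of null networks to sample (>= 1).
#' @param swaps_per_sample Accepted swaps between successive samples (>= 1).
#' @param burn_in_swaps Accepted swaps before the first sample.
#' @param seed Optional integer seed; identical config + seed reproduces the
#'   network stream bit-identically.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_networks = 5000L, swaps_per_sample = 100L,
                        burn_in_swaps = 1000L, seed = NULL) {
  stopifnot(n_networks >= 1, swaps_per_sample >= 1, burn_in_swaps >= 0)
  structure(list(n_networks = as.integer(n_networks),
                 swaps_per_sample = as.integer(swaps_per_sample),
                 burn_in_swaps = as.integer(burn_in_swaps),
                 seed = seed),
            class = "perm_config")
}

#' Mutable permutation state over a group-by-individual matrix
#'
#' Builds the swappable observation table: every (event, bat) observation is
#' indexed by its stratum — the (population, roost, year) of its event. The
#' returned environment is mutated in place by [attempt_swap()] and the
#' network generator; create it from a `gbi` whenever a fresh chain is needed.
#'
#' @param gbi A group-by-individual object from [build_gbi()].
#' @return An environment of class `perm_state` with fields `M` (membership
#'   matrix copy), `strat_event`/`strat_bat` (per-stratum observation lists),
#'   `eligible` (strata with >= 2 observations), `events`, `bats`, and
#'   counters `accepted`/`attempts`.
#' @export
perm_state <- function(gbi) {
  stopifnot(inherits(gbi, "gbi"))
  M <- matrix(as.integer(gbi$M), nrow(gbi$M), ncol(gbi$M),
              dimnames = dimnames(gbi$M))
  obs <- which(M == 1L, arr.ind = TRUE)
  stratum <- paste(gbi$events$population, gbi$events$roost_id, gbi$events$year,
                   sep = "|")[obs[, 1]]
  strat_event <- split(as.integer(obs[, 1]), stratum)
  strat_bat <- split(as.integer(obs[, 2]), stratum)
  sizes <- lengths(strat_event)
  eligible <- as.integer(which(sizes >= 2))
  # a swap is only ever possible if some stratum spans >= 2 distinct events
  spans <- vapply(strat_event, function(e) length(unique(e)) >= 2, logical(1))
  if (!any(spans & sizes >= 2)) {
    stop("no stratum (population x roost x year) contains observations from two ",
         "distinct events; datastream permutation is impossible on this dataset — ",
         "a larger or denser dataset is required", call. = FALSE)
  }
  st <- new.env(parent = emptyenv())
  st$M <- M
  st$strat_event <- strat_event
  st$strat_bat <- strat_bat
  st$eligible <- eligible
  st$events <- gbi$events
  st$bats <- gbi$bats
  st$accepted <- 0
  st$attempts <- 0
  class(st) <- "perm_state"
  st
}

#' Propose one constrained observation swap
#'
#' Draws one stratum uniformly from the eligible strata (those holding at
#' least two observations), then two observations uniformly from it, and
#' exchanges the two bat identities iff the two events differ, the bats
#' differ, and neither bat already belongs to the other's event; otherwise the
#' proposal is rejected and the state is unchanged. The state is modified in
#' place; rejections are counted in `state$attempts`.
#'
#' @param state A `perm_state`.
#' @return `state`, invisibly; `state$last_accepted` reports whether the
#'   proposal was accepted.
#' @export
attempt_swap <- function(state) {
  res <- swap_engine(state$M, state$strat_event, state$strat_bat,
                     state$eligible, 1L, 1, TRUE)
  state$accepted <- state$accepted + res$accepted
  state$attempts <- state$attempts + res$attempts
  state$last_accepted <- res$accepted == 1L
  invisible(state)
}

# Run `n_accept` accepted swaps on the state (in place).
run_swaps <- function(state, n_accept) {
  if (n_accept <= 0) return(invisible(state))
  res <- swap_engine(state$M, state$strat_event, state$strat_bat,
                     state$eligible, as.integer(n_accept),
                     max(1e6, 10000 * n_accept), FALSE)
  state$accepted <- state$accepted + res$accepted
  state$attempts <- state$attempts + res$attempts
  invisible(state)
}

# gbi with the state's current membership matrix (copied).
state_gbi <- function(state) {
  structure(list(M = state$M + 0L, events = state$events, bats = state$bats),
            class = "gbi")
}

#' Generate null association networks by datastream permutation
#'
#' Runs the constrained swap chain ([attempt_swap()]) starting from the
#' observed group-by-individual matrix: after `burn_in_swaps` accepted swaps,
#' one network is emitted every `swaps_per_sample` accepted swaps,
#' `n_networks` times. Each emission is converted to a simple-ratio
#' association matrix; if `fun` is supplied it is called as
#' `fun(assoc, gbi)` on each emission and its results are returned instead of
#' the matrices (use this to stream statistics without storing every
#' network).
#'
#' @param gbi A group-by-individual object.
#' @param config A [perm_config()].
#' @param fun Optional function of `(assoc, gbi)` evaluated at each emission.
#' @param period Sampling-period convention passed to [simple_ratio_index()].
#' @return A list of length `n_networks` (association matrices, or `fun`
#'   results), with attributes `accepted` and `attempts` (swap counts).
#' @export
generate_null_networks <- function(gbi, config = perm_config(), fun = NULL,
                                   period = c("date-population", "event")) {
  period <- match.arg(period)
  stopifnot(inherits(config, "perm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- perm_state(gbi)
  run_swaps(st, config$burn_in_swaps)
  out <- vector("list", config$n_networks)
  for (k in seq_len(config$n_networks)) {
    run_swaps(st, config$swaps_per_sample)
    g <- state_gbi(st)
    a <- simple_ratio_index(g, period = period)
    out[[k]] <- if (is.null(fun)) a else fun(a, g)
  }
  attr(out, "accepted") <- st$accepted
  attr(out, "attempts") <- st$attempts
  out
}

#' Empirical p-value from a null distribution
#'
#' One-sided p is the proportion of null statistics at least as extreme as the
#' observed one (ties count as extreme); the two-sided value doubles the
#' smaller tail, capped at 1. When the tail count is zero the p-value is
#' reported as a bound, `"< 1/n"`.
#'
#' @param observed Observed statistic (finite scalar).
#' @param nulls Numeric vector of null statistics (non-empty).
#' @param alternative `"two-sided-doubled"` (default), `"greater"` or
#'   `"less"`.
#' @return A list of class `empirical_p`: `p_value` (numeric; 0 when the tail
#'   count is zero), `p_display` (string, `"< 1/n"` form when bounded),
#'   `bounded` (logical), `n_null`, `alternative`.
#' @export
empirical_p <- function(observed, nulls,
                        alternative = c("two-sided-doubled", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(nulls) >= 1, length(observed) == 1)
  n <- length(nulls)
  n_ge <- sum(nulls >= observed)
  n_le <- sum(nulls <= observed)
  p_greater <- n_ge / n
  p_less <- n_le / n
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              `two-sided-doubled` = min(1, 2 * min(p_greater, p_less)))
  tail_count <- switch(alternative,
                       greater = n_ge, less = n_le,
                       `two-sided-doubled` = min(n_ge, n_le))
  bounded <- tail_count == 0
  p_display <- if (bounded) sprintf("< %.4g", 1 / n) else sprintf("%.4g", p)
  structure(list(p_value = p, p_display = p_display, bounded = bounded,
                 n_null = n, alternative = alternative),
            class = "empirical_p")
}

#' @export
print.empirical_p <- function(x, ...) {
  cat(sprintf("empirical p (%s, %d nulls): %s\n",
              x$alternative, x$n_null,
              if (x$bounded) x$p_display else x$p_display))
  invisible(x)
}

# Conservation checks on a permutation state / permuted gbi against the
# original: event sizes, per-bat sighting counts, per-bat stratum visit
# counts, and within-event uniqueness. Returns TRUE or a character message.
check_conservation <- function(M0, M1, events) {
  if (!all(M1 %in% c(0L, 1L))) return("membership entries outside {0,1}")
  if (!identical(rowSums(M0), rowSums(M1))) return("event sizes changed")
  if (!identical(colSums(M0), colSums(M1))) return("per-bat sighting counts changed")
  stratum <- paste(events$population, events$roost_id, events$year, sep = "|")
  v0 <- rowsum(M0, stratum)
  v1 <- rowsum(M1, stratum)
  if (!identical(v0, v1)) return("per-bat stratum visit counts changed")
  TRUE
}
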