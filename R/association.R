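#' Build a group-by-individual matrix
#'
#' One row per capture event, one column per bat; entry 1 when the bat was a
#' member of the event. Events are ordered by date then roost id, bats
#' lexicographically, so the construction is deterministic and independent of
#' record order.
#'
#' @param ds A `capture_dataset` (already filtered to the analysis set).
#' @return An object of class `gbi`: list with binary matrix `M`
#'   (events x bats, dimnames set), `events` (event metadata: `event_id`,
#'   `date`, `roost_id`, `population`, `year`) and `bats` (per-bat metadata:
#'   `bat_id`, `sex`, `population`, `n_sightings`).
#' @export
build_gbi <- function(ds) {
  stopifnot(inherits(ds, "capture_dataset"))
  if (nrow(ds$captures) == 0) stop("cannot build a group-by-individual matrix from an empty dataset")
  events <- ds$events |> dplyr::arrange(.data$date, .data$roost_id)
  bats <- ds$captures |>
    dplyr::group_by(.data$bat_id) |>
    dplyr::summarise(sex = .data$sex[1], population = .data$population[1],
                     n_sightings = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$bat_id)
  M <- matrix(0L, nrow(events), nrow(bats),
              dimnames = list(events$event_id, bats$bat_id))
  M[cbind(match(ds$captures$event_id, events$event_id),
          match(ds$captures$bat_id, bats$bat_id))] <- 1L
  structure(list(M = M, events = events, bats = bats), class = "gbi")
}

#' @export
print.gbi <- function(x, ...) {
  cat(sprintf("<gbi> %d events x %d bats (%d observations)\n",
              nrow(x$M), ncol(x$M), sum(x$M)))
  invisible(x)
}

#' Simple ratio index of dyadic association
#'
#' For each dyad, over sampling periods, counts `x` (periods in which the two
#' bats shared a group), `y_ab` (periods in which both were observed but never
#' together), and `y_a`, `y_b` (periods in which only one was observed); the
#' index is `x / (x + y_ab + y_a + y_b)` — the probability of observing the
#' pair together given that at least one was seen. The default sampling period
#' is the (date, population) combination, so two bats captured the same day in
#' different roosts of one population count as "both observed, apart";
#' `period = "event"` treats each capture event as its own period instead.
#'
#' @param gbi A group-by-individual object from [build_gbi()].
#' @param period Sampling-period convention, `"date-population"` (default) or
#'   `"event"`.
#' @return An object of class `assoc_matrix`: list with symmetric matrices
#'   `sri` (index, `NA` where the denominator is 0), `denom` (per-dyad
#'   denominators), `together` (joint-observation counts) and the `bats`
#'   metadata tibble.
#' @export
simple_ratio_index <- function(gbi, period = c("date-population", "event")) {
  period <- match.arg(period)
  M <- gbi$M
  pid <- if (period == "event") as.character(seq_len(nrow(M))) else
    paste(gbi$events$date, gbi$events$population, sep = "|")

  seen_count <- rowsum(M, group = pid, reorder = FALSE)
  S <- (seen_count > 0) * 1
  B <- crossprod(S)                 # periods with both bats observed
  n_seen <- colSums(S)              # periods with the bat observed
  D <- outer(n_seen, n_seen, "+") - B

  if (max(seen_count) <= 1L) {
    # no bat appears twice within a period: event-level crossprod is exact
    X <- crossprod(M)
  } else {
    X <- matrix(0, ncol(M), ncol(M), dimnames = list(colnames(M), colnames(M)))
    for (p in unique(pid)) {
      Mp <- M[pid == p, , drop = FALSE]
      X <- X + (crossprod(Mp) > 0)
    }
  }

  sri <- X / D
  sri[D == 0] <- NA_real_
  diag(sri) <- NA_real_
  storage.mode(X) <- "double"
  structure(list(sri = sri, denom = D, together = X, bats = gbi$bats,
                 period = period),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  v <- x$sri[lower.tri(x$sri)]
  v <- v[!is.na(v)]
  cat(sprintf("<assoc_matrix> %d bats | %d defined dyads | mean SRI %.3f | period: %s\n",
              nrow(x$sri), length(v), if (length(v)) mean(v) else NA_real_, x$period))
  invisible(x)
}

#' @export
tidy.assoc_matrix <- function(x, ...) {
  ids <- rownames(x$sri)
  idx <- which(lower.tri(x$sri), arr.ind = TRUE)
  tibble::tibble(
    bat_1 = ids[idx[, 2]], bat_2 = ids[idx[, 1]],
    sri = x$sri[idx], together = x$together[idx], denom = x$denom[idx]
  )
}

#' Social differentiation: coefficient of variation of the SRI
#'
#' Variability of dyadic association across a set of dyads, computed as
#' sd/mean of the simple ratio index over defined (and optionally masked)
#' off-diagonal dyads, each unordered dyad counted once. The population
#' standard deviation (divide by the number of dyads) is the default
#' convention; `sd_type = "sample"` switches to the n-1 denominator.
#'
#' @param assoc An `assoc_matrix` (or a plain symmetric matrix).
#' @param dyad_mask Optional binary/logical symmetric matrix selecting the
#'   dyads to include.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return The coefficient of variation (dimensionless); `NA` with a warning
#'   if fewer than two dyads are defined or the mean index is zero.
#' @export
social_differentiation <- function(assoc, dyad_mask = NULL,
                                   sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  sri <- if (inherits(assoc, "assoc_matrix")) assoc$sri else assoc
  keep <- lower.tri(sri) & !is.na(sri)
  if (!is.null(dyad_mask)) keep <- keep & (dyad_mask > 0)
  v <- sri[keep]
  if (length(v) < 2) {
    warning("fewer than two defined dyads; social differentiation undefined")
    return(NA_real_)
  }
  m <- mean(v)
  if (m == 0) {
    warning("mean association is zero; social differentiation undefined")
    return(NA_real_)
  }
  s <- if (sd_type == "population") sqrt(mean((v - m)^2)) else sd(v)
  s / m
}

#' Dyad mask restricted to a subset of bats (optionally one sex)
#'
#' Convenience for subset analyses: a symmetric logical matrix over the
#' association matrix's bats that is TRUE exactly for dyads whose both members
#' are in `bat_ids` (and of sex `sex`, if given).
#'
#' @param assoc An `assoc_matrix`.
#' @param bat_ids Bats to include (default all).
#' @param sex Optional `"female"` or `"male"` restriction.
#' @return A logical symmetric matrix.
#' @export
dyad_mask <- function(assoc, bat_ids = NULL, sex = NULL) {
  bats <- assoc$bats
  keep <- rep(TRUE, nrow(bats))
  if (!is.null(bat_ids)) keep <- keep & bats$bat_id %in% bat_ids
  if (!is.null(sex)) keep <- keep & bats$sex %in% sex
  outer(keep, keep, "&")
}

#' Write an association matrix (and its denominators)
#'
#' Square-matrix CSVs in the same dialect as [write_relatedness()]: `path`
#' receives the SRI matrix and `paste0(path-sans-ext, "_denom.csv")` the
#' per-dyad denominator counts.
#'
#' @param assoc An `assoc_matrix`.
#' @param path Output path for the SRI matrix.
#' @return Paths written, invisibly.
#' @export
write_association <- function(assoc, path) {
  write_square_matrix(assoc$sri, path)
  denom_path <- sub("\\.csv$", "_denom.csv", path)
  if (identical(denom_path, path)) denom_path <- paste0(path, "_denom.csv")
  write_square_matrix(assoc$denom, denom_path)
  invisible(c(path, denom_path))
}
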