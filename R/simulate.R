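#' Simulate daily roosting groups
#'
#' Each simulated day, within each population, the individuals present assort
#' into `groups_per_day` groups, one roost per group. Bats arrive in random
#' order and each joins the group maximising
#' `pi * mean(past association with members) + kappa * mean(relatedness to
#' members)` (the kin term applies to females only) plus Gaussian noise;
#' an empty group scores zero plus noise. With `kappa = pi = 0` assembly is
#' therefore uniform-random — the calibration null. Juveniles roost with their
#' mother. Groups occasionally relocate wholesale to an empty roost
#' (`roost_switch_prob` per group per day), producing fission-fusion roost
#' switching among nearby roosts.
#'
#' @param ped A [simulate_pedigree()] pedigree.
#' @param cfg The [sim_config()] used to build it.
#' @param relatedness Optional true relatedness matrix (computed noise-free
#'   from the pedigree when omitted and `kin_bias > 0`).
#' @param registry Optional roost registry; a fresh planar one is generated
#'   when omitted.
#' @return A tibble of true daily memberships: `year`, `day`, `population`,
#'   `group`, `roost_id`, `bat_id`, `age_class`.
#' @export
simulate_roosting <- function(ped, cfg, relatedness = NULL, registry = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  kappa <- cfg$kin_bias
  pi_w <- cfg$partner_preference
  need_scores <- kappa > 0 || pi_w > 0
  if (need_scores && is.null(relatedness)) relatedness <- pedigree_relatedness(ped, 0)
  n_all <- nrow(ped)
  idx_of <- setNames(seq_len(n_all), ped$id)
  R <- if (need_scores) relatedness[ped$id, ped$id] else NULL
  C <- if (pi_w > 0) matrix(0, n_all, n_all) else NULL

  if (is.null(registry)) registry <- make_roost_registry(cfg)
  acc <- list()
  ai <- 0
  for (pop in unique(ped$population)) {
    pop_roosts <- registry$roost_id[registry$population == pop]
    G <- cfg$groups_per_day
    days_seen <- 0
    group_roost <- NULL
    for (y in seq_len(cfg$n_years)) {
      present <- pedigree_present(ped, y) & ped$population == pop
      adults <- which(present & ped$birth_year < y)
      juvs <- which(present & ped$birth_year == y)
      if (length(adults) == 0) next
      if (is.null(group_roost)) group_roost <- sample(pop_roosts, G)
      for (d in seq_len(cfg$days_per_year)) {
        # wholesale group relocation to an empty roost
        for (g in seq_len(G)) {
          if (runif(1) < cfg$roost_switch_prob) {
            empty <- setdiff(pop_roosts, group_roost)
            if (length(empty) > 0) group_roost[g] <- sample(empty, 1)
          }
        }
        if (!need_scores) {
          grp <- sample.int(G, length(adults), replace = TRUE)
        } else {
          # preference model: groups have a soft capacity (1.5x the balanced
          # size) so preferred cliques persist instead of the whole population
          # snowballing into one group
          cap <- max(2, ceiling(1.5 * length(adults) / G))
          grp <- integer(length(adults))
          members <- vector("list", G)
          order_in <- sample(seq_along(adults))
          is_f <- ped$sex[adults] == "female"
          for (k in order_in) {
            b <- adults[k]
            score <- vapply(members, function(m) {
              if (length(m) == 0) return(0)
              s <- 0
              if (pi_w > 0 && days_seen > 0) s <- s + pi_w * mean(C[b, m]) / days_seen
              if (kappa > 0 && is_f[k]) s <- s + kappa * mean(R[b, m])
              s
            }, numeric(1))
            open <- lengths(members) < cap
            score <- score + rnorm(G, 0, cfg$choice_noise_sd)
            score[!open] <- -Inf
            g <- which.max(score)
            grp[k] <- g
            members[[g]] <- c(members[[g]], b)
          }
        }
        # juveniles roost with their mother
        jg <- integer(0)
        if (length(juvs) > 0) {
          mom <- idx_of[ped$mother_id[juvs]]
          jg <- grp[match(mom, adults)]
          jg[is.na(jg)] <- sample.int(G, sum(is.na(jg)), replace = TRUE)
        }
        all_idx <- c(adults, juvs)
        all_grp <- c(grp, jg)
        if (pi_w > 0) {
          for (g in unique(all_grp)) {
            m <- all_idx[all_grp == g]
            if (length(m) > 1) C[m, m] <- C[m, m] + 1
          }
        }
        days_seen <- days_seen + 1
        ai <- ai + 1
        acc[[ai]] <- tibble::tibble(
          year = y, day = d, population = pop,
          group = all_grp, roost_id = group_roost[all_grp],
          bat_id = ped$id[all_idx],
          age_class = ifelse(ped$birth_year[all_idx] == y, "juvenile", "adult")
        )
      }
    }
  }
  if (length(acc) == 0) {
    warning("no individuals present in any simulated year; empty roosting record")
    return(tibble::tibble(year = integer(), day = integer(),
                          population = character(), group = integer(),
                          roost_id = character(), bat_id = character(),
                          age_class = character()))
  }
  dplyr::bind_rows(acc)
}

# Planar roost registry: two population centres 5 km apart, roosts scattered
# within a ~400 m box (matching the within-population roost spacing the
# analysis expects, ~0.08-0.45 km).
make_roost_registry <- function(cfg) {
  pops <- c("P1", "P2")
  centres <- c(0, 5000)
  out <- purrr::map_dfr(seq_along(pops), function(i) {
    tibble::tibble(
      roost_id = sprintf("%sR%02d", pops[i], seq_len(cfg$n_roosts)),
      population = pops[i],
      x = centres[i] + runif(cfg$n_roosts, 0, 400),
      y = runif(cfg$n_roosts, 0, 400)
    )
  })
  attr(out, "coord_system") <- "planar"
  out
}

#' Sample capture events from the true roosting record
#'
#' Emulates opportunistic roost captures: on each sampled (year, day,
#' population) occasion one occupied roost is netted and every bat present is
#' recorded independently with probability `detection_prob` (escapes drop the
#' bat from the event; an event with no detections is dropped). Reproductive
#' status is assigned at capture (adult males scrotal with
#' `male_repro_prob`).
#'
#' @param truth Roosting record from [simulate_roosting()].
#' @param ped The pedigree.
#' @param cfg The [sim_config()].
#' @param roosts Roost registry (from the simulation bundle).
#' @return A `capture_dataset`; the drawn occasions are kept in attribute
#'   `occasions` for oracle tests.
#' @export
sample_captures <- function(truth, ped, cfg, roosts) {
  if (nrow(truth) == 0) {
    warning("empty roosting record; returning an empty capture dataset")
    empty <- tibble::tibble(bat_id = character(), date = as.Date(character()),
                            roost_id = character(), population = character(),
                            sex = character(), age_class = character(),
                            repro_status = character())
    return(as_capture_dataset(empty, roosts = roosts))
  }
  occasions <- truth |>
    dplyr::distinct(.data$year, .data$day, .data$population) |>
    dplyr::group_by(.data$year) |>
    dplyr::slice_sample(n = cfg$captures_per_year) |>
    dplyr::ungroup()

  day_spacing <- max(1L, floor(364 / cfg$days_per_year))
  sex_of <- setNames(ped$sex, ped$id)
  rows <- purrr::map_dfr(seq_len(nrow(occasions)), function(i) {
    oc <- occasions[i, ]
    present <- truth |>
      dplyr::filter(.data$year == oc$year, .data$day == oc$day,
                    .data$population == oc$population)
    roost <- sample(unique(present$roost_id), 1)
    members <- present |> dplyr::filter(.data$roost_id == roost)
    detected <- runif(nrow(members)) < cfg$detection_prob
    if (!any(detected)) return(NULL)
    members <- members[detected, ]
    date <- as.Date(sprintf("%d-01-01", cfg$base_year + oc$year - 1)) +
      (oc$day - 1) * day_spacing
    sx <- sex_of[members$bat_id]
    repro <- dplyr::case_when(
      members$age_class == "juvenile" ~ NA_character_,
      sx == "male" ~ ifelse(runif(nrow(members)) < cfg$male_repro_prob,
                            "scrotal", "nonreproductive"),
      TRUE ~ sample(c("pregnant", "lactating", "nonreproductive"),
                    nrow(members), replace = TRUE, prob = c(0.15, 0.25, 0.6))
    )
    tibble::tibble(
      bat_id = members$bat_id, date = date, roost_id = roost,
      population = oc$population, sex = unname(sx),
      age_class = members$age_class, repro_status = repro
    )
  })
  ds <- as_capture_dataset(rows, roosts = roosts)
  attr(ds, "occasions") <- occasions
  ds
}

#' Simulate a full colony study
#'
#' End-to-end generator: pedigree, true relatedness, roost registry, daily
#' roosting record, sampled capture dataset, and the emitted (optionally
#' noisy) relatedness matrix — everything the analysis pipeline consumes, with
#' ground truth retained for calibration and power studies.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `roost_simulation`: list with `dataset`
#'   (a `capture_dataset` including the registry), `relatedness` (emitted
#'   matrix), `relatedness_true` (noise-free), `pedigree`, `truth` (daily
#'   memberships), `roosts`, `config`.
#' @export
simulate_colony <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ped <- simulate_pedigree(strip_seed(cfg))
  r_true <- pedigree_relatedness(ped, 0)
  registry <- make_roost_registry(cfg)
  truth <- simulate_roosting(ped, strip_seed(cfg), r_true, registry)
  ds <- sample_captures(truth, ped, cfg, registry)
  r_obs <- pedigree_relatedness(ped, cfg$relatedness_noise_sd)
  structure(list(dataset = ds, relatedness = r_obs, relatedness_true = r_true,
                 pedigree = ped, truth = truth, roosts = registry,
                 config = cfg),
            class = "roost_simulation")
}

# sim_config with the seed removed, so nested generators do not reseed.
strip_seed <- function(cfg) {
  cfg$seed <- NULL
  cfg
}

#' @export
print.roost_simulation <- function(x, ...) {
  cat(sprintf("<roost_simulation> %d individuals | %d capture records | kappa=%.2g pi=%.2g\n",
              nrow(x$pedigree), nrow(x$dataset$captures),
              x$config$kin_bias, x$config$partner_preference))
  invisible(x)
}

#' Write a simulation bundle to disk
#'
#' Emits `captures.csv`, `roosts.csv`, `relatedness.csv` in the package's
#' canonical dialects plus `truth.json` (pedigree, true daily memberships,
#' config echo including the seed).
#'
#' @param sim A [simulate_colony()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_captures(sim$dataset, file.path(dir, "captures.csv"))
  write_roosts(sim$roosts, file.path(dir, "roosts.csv"))
  write_relatedness(sim$relatedness, file.path(dir, "relatedness.csv"))
  truth <- list(
    config = unclass(sim$config),
    pedigree = as.data.frame(sim$pedigree),
    daily_memberships = as.data.frame(sim$truth)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
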