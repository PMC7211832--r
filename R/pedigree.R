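#' Simulation configuration
#'
#' Parameters of the colony simulator. Defaults emulate the study system the
#' analysis tools assume: two closed populations of roosts, overlapping
#' generations over six years, one pup per female-year at most, male-biased
#' dispersal (dispersing males leave the study area), female philopatry,
#' fission-fusion roost switching among nearby roosts, and imperfect per-event
#' capture. `kin_bias` (kappa) and `partner_preference` (pi) control the
#' strength of kin-biased grouping (females only) and of stable partner
#' preferences in both sexes; with both zero, group assembly is
#' uniform-random — the calibration null.
#'
#' @param n_founders Founding adults, split evenly across two populations and
#'   sexes.
#' @param n_years Simulated years (capture effort spans all of them).
#' @param n_roosts Roosts per population.
#' @param pup_rate Probability an adult female produces one pup in a year.
#' @param male_dispersal_prob Probability a male leaves the study area on
#'   reaching sexual maturity (the end of his first adult year). The default
#'   is near-complete male dispersal: locally born males are essentially never
#'   seen as older adults.
#' @param female_dispersal_prob Ditto for females (default 0: philopatry).
#' @param kin_bias kappa >= 0: weight of mean relatedness to a group's members
#'   in a female's group choice.
#' @param partner_preference pi >= 0: weight of mean past association with a
#'   group's members in any bat's group choice.
#' @param choice_noise_sd Standard deviation of the Gaussian noise added to
#'   each group's choice score (sets the scale of kappa and pi).
#' @param roost_switch_prob Daily probability a whole group relocates to an
#'   empty roost.
#' @param groups_per_day Roosting groups formed per population per day.
#' @param days_per_year Roosting days simulated per year (weekly snapshots by
#'   default).
#' @param captures_per_year Capture events (group captures) per year.
#' @param detection_prob Per-bat detection probability at a captured roost.
#' @param relatedness_noise_sd Truncated-Gaussian noise added to the emitted
#'   relatedness matrix, emulating marker-based estimation error.
#' @param male_repro_prob Probability an adult male is recorded as scrotal at
#'   capture.
#' @param base_year Calendar year of simulation year 1.
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 60, n_years = 6, n_roosts = 16,
                       pup_rate = 0.5, male_dispersal_prob = 0.95,
                       female_dispersal_prob = 0, kin_bias = 0,
                       partner_preference = 0, choice_noise_sd = 1,
                       roost_switch_prob = 0.25, groups_per_day = 8,
                       days_per_year = 52, captures_per_year = 18,
                       detection_prob = 0.85, relatedness_noise_sd = 0.05,
                       male_repro_prob = 0.6, base_year = 2013, seed = NULL) {
  stopifnot(all(c(pup_rate, male_dispersal_prob, female_dispersal_prob,
                  roost_switch_prob, detection_prob, male_repro_prob) >= 0),
            all(c(pup_rate, male_dispersal_prob, female_dispersal_prob,
                  roost_switch_prob, detection_prob, male_repro_prob) <= 1),
            kin_bias >= 0, partner_preference >= 0,
            n_founders >= 2, n_years >= 0, n_roosts >= groups_per_day,
            groups_per_day >= 1, days_per_year >= 1)
  structure(mget(names(formals())), class = "sim_config")
}

#' Simulate a pedigree with overlapping generations
#'
#' Two closed populations; founders are adults in year 1; each adult female
#' produces at most one pup per year (probability `pup_rate`), sired by a
#' random resident adult male of her population. Individuals are juveniles in
#' their birth year and adults from the next; on reaching sexual maturity at
#' the end of the first adult year, males (and optionally females) leave the
#' study area with the configured dispersal probability — so dispersing males
#' can be recaptured as young adults but never as older ones. Dispersing
#' individuals are removed, never relocated, so populations stay closed.
#'
#' @param cfg A [sim_config()].
#' @return A tibble of class `pedigree`: `id`, `sex`, `mother_id`,
#'   `father_id`, `birth_year` (founders 0), `population`, `dispersed_year`
#'   (`NA` for residents).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n0 <- cfg$n_founders
  founders <- tibble::tibble(
    id = sprintf("B%04d", seq_len(n0)),
    sex = rep(c("female", "male"), length.out = n0),
    mother_id = NA_character_, father_id = NA_character_,
    birth_year = 0L,
    population = rep(c("P1", "P2"), each = ceiling(n0 / 2))[seq_len(n0)],
    dispersed_year = NA_integer_
  )
  ped <- founders
  counter <- n0
  for (y in seq_len(cfg$n_years)) {
    # cohort born in y-2 reaches sexual maturity after its first adult year
    # and may disperse at the start of year y
    maturing <- which(ped$birth_year == y - 2L & ped$birth_year > 0L)
    if (length(maturing) > 0) {
      p_disp <- ifelse(ped$sex[maturing] == "male",
                       cfg$male_dispersal_prob, cfg$female_dispersal_prob)
      goes <- runif(length(maturing)) < p_disp
      ped$dispersed_year[maturing[goes]] <- y
    }
    present <- is.na(ped$dispersed_year) | ped$dispersed_year > y
    adult <- ped$birth_year < y
    new_pups <- list()
    for (pop in unique(ped$population)) {
      in_pop <- ped$population == pop
      mothers <- which(in_pop & present & adult & ped$sex == "female")
      fathers <- ped$id[in_pop & present & adult & ped$sex == "male"]
      if (length(mothers) == 0 || length(fathers) == 0) next
      breeding <- mothers[runif(length(mothers)) < cfg$pup_rate]
      if (length(breeding) == 0) next
      pups <- tibble::tibble(
        id = sprintf("B%04d", counter + seq_along(breeding)),
        sex = ifelse(runif(length(breeding)) < 0.5, "female", "male"),
        mother_id = ped$id[breeding],
        father_id = sample(fathers, length(breeding), replace = TRUE),
        birth_year = y,
        population = pop,
        dispersed_year = NA_integer_
      )
      counter <- counter + length(breeding)
      new_pups[[pop]] <- pups
    }
    if (length(new_pups) > 0) ped <- dplyr::bind_rows(ped, unname(new_pups))
  }
  alive_now <- sum(is.na(ped$dispersed_year) | ped$dispersed_year > cfg$n_years)
  if (alive_now == 0) warning("population extinct; returning a partial pedigree")
  class(ped) <- c("pedigree", class(ped))
  ped
}

# Individuals present (born, not yet dispersed) in a given year.
pedigree_present <- function(ped, year) {
  ped$birth_year <= year & (is.na(ped$dispersed_year) | ped$dispersed_year > year)
}

#' Pedigree relatedness matrix
#'
#' Dyadic relatedness r = 2 x kinship, computed by the standard recursive
#' kinship algorithm over the pedigree (parent-offspring and full siblings
#' 0.5, half siblings 0.25, with inbreeding handled through the recursion).
#' Optional truncated-Gaussian noise, clamped back to [0, 1], emulates
#' marker-based estimation error; the diagonal is set to 1 and ignored by all
#' analyses.
#'
#' @param ped A [simulate_pedigree()] pedigree (parents must be listed; any
#'   order).
#' @param noise_sd Standard deviation of the symmetric off-diagonal noise
#'   (0 = exact pedigree relatedness).
#' @return A symmetric numeric matrix keyed by individual id.
#' @export
pedigree_relatedness <- function(ped, noise_sd = 0) {
  ord <- order(ped$birth_year)
  ids <- ped$id[ord]
  n <- length(ids)
  mi <- match(ped$mother_id[ord], ids)
  fi <- match(ped$father_id[ord], ids)
  K <- matrix(0, n, n)
  kin <- function(a, b) if (is.na(a) || is.na(b)) 0 else K[a, b]
  for (i in seq_len(n)) {
    if (i > 1) {
      prev <- seq_len(i - 1)
      km <- if (is.na(mi[i])) rep(0, i - 1) else K[mi[i], prev]
      kf <- if (is.na(fi[i])) rep(0, i - 1) else K[fi[i], prev]
      K[i, prev] <- 0.5 * (km + kf)
      K[prev, i] <- K[i, prev]
    }
    K[i, i] <- 0.5 * (1 + kin(mi[i], fi[i]))
  }
  r <- 2 * K
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  if (noise_sd > 0) {
    noise <- matrix(0, n, n)
    noise[lower.tri(noise)] <- rnorm(n * (n - 1) / 2, 0, noise_sd)
    noise <- noise + t(noise)
    r <- pmax(pmin(r + noise, 1), 0)
    diag(r) <- 1
  }
  r[ped$id, ped$id]
}
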