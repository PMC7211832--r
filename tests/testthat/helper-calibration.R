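# Shared replicate functions for the calibration and parameter-recovery
# studies. Problem sizes are reduced relative to the full study scale so that
# Monte-Carlo studies with hundreds of replicates stay cheap; the methods
# vignette documents the choices.

# Single-predictor OLS slope over defined lower-triangle dyads.
dyad_slope <- function(Y, X) {
  m <- lower.tri(Y) & is.finite(Y) & is.finite(X)
  if (sum(m) < 3 || sd(X[m]) == 0) return(NA_real_)
  stats::cov(X[m], Y[m]) / stats::var(X[m])
}

# One no-preference (kappa = pi = 0) dataset; returns the datastream-null
# p-values of the social-differentiation CV test and of the female-subset
# QAP relatedness slope (200 null networks each).
calibration_rep <- function(seed, n_networks = 200) {
  cfg <- sim_config(n_founders = 16, n_years = 3, n_roosts = 6,
                    groups_per_day = 3, days_per_year = 26,
                    captures_per_year = 15, pup_rate = 0.8, seed = seed)
  sim <- simulate_colony(cfg)
  ds <- filter_captures(sim$dataset, min_sightings = 4)
  if (dplyr::n_distinct(ds$captures$bat_id) < 6) return(c(NA_real_, NA_real_))
  gbi <- build_gbi(ds)
  ids <- gbi$bats$bat_id
  fids <- ids[gbi$bats$sex == "female"]
  if (length(fids) < 4) return(c(NA_real_, NA_real_))
  rel <- sim$relatedness[ids, ids]
  stat <- function(a, g) c(
    cv = suppressWarnings(social_differentiation(a)),
    beta_f = dyad_slope(a$sri[fids, fids], rel[fids, fids]))
  obs <- stat(simple_ratio_index(gbi), gbi)
  nulls <- do.call(rbind, generate_null_networks(gbi, perm_config(n_networks),
                                                 fun = stat))
  p_of <- function(k) {
    nb <- nulls[!is.na(nulls[, k]), k]
    if (is.na(obs[k]) || length(nb) < n_networks / 2) return(NA_real_)
    empirical_p(obs[k], nb)$p_value
  }
  c(cv = p_of(1), beta_f = p_of(2))
}

# One kin-biased dataset at the documented recovery point (kappa = 14 for
# females, pi = 2, all other settings at the study-scale defaults); returns
# the observed female/male relatedness slopes and their datastream-null
# p-values.
power_rep <- function(seed, kappa = 14, pi_w = 2, n_networks = 200) {
  cfg <- sim_config(kin_bias = kappa, partner_preference = pi_w, seed = seed)
  sim <- simulate_colony(cfg)
  ds <- filter_captures(sim$dataset, min_sightings = 4)
  gbi <- build_gbi(ds)
  ids <- gbi$bats$bat_id
  fids <- ids[gbi$bats$sex == "female"]
  mids <- ids[gbi$bats$sex == "male"]
  if (length(fids) < 5 || length(mids) < 5) return(rep(NA_real_, 4))
  rel <- sim$relatedness[ids, ids]
  stat <- function(a, g) c(
    beta_f = dyad_slope(a$sri[fids, fids], rel[fids, fids]),
    beta_m = dyad_slope(a$sri[mids, mids], rel[mids, mids]))
  obs <- stat(simple_ratio_index(gbi), gbi)
  nulls <- do.call(rbind, generate_null_networks(gbi, perm_config(n_networks),
                                                 fun = stat))
  p_of <- function(k) {
    nb <- nulls[!is.na(nulls[, k]), k]
    if (is.na(obs[k]) || length(nb) < n_networks / 2) return(NA_real_)
    empirical_p(obs[k], nb)$p_value
  }
  c(beta_f = unname(obs[1]), p_f = p_of(1),
    beta_m = unname(obs[2]), p_m = p_of(2))
}
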