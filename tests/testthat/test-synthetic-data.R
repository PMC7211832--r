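test_that("pedigree respects dispersal and fecundity settings", {
  cfg <- sim_config(n_founders = 30, n_years = 4, male_dispersal_prob = 1,
                    seed = 1)
  ped <- simulate_pedigree(cfg)
  # every locally born male disperses at maturity: none remains beyond his
  # first adult year
  local_males <- ped[!is.na(ped$mother_id) & ped$sex == "male", ]
  mature_by_end <- local_males$birth_year <= cfg$n_years - 2
  expect_true(all(!is.na(local_males$dispersed_year[mature_by_end])))
  expect_true(all(local_males$dispersed_year[mature_by_end] ==
                    local_males$birth_year[mature_by_end] + 2))

  cfg0 <- sim_config(n_founders = 10, n_years = 5, pup_rate = 0, seed = 2)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 10)

  # sex ratio at birth ~ 0.5
  cfgb <- sim_config(n_founders = 100, n_years = 6, pup_rate = 1,
                     male_dispersal_prob = 0, seed = 3)
  pedb <- simulate_pedigree(cfgb)
  born <- pedb[!is.na(pedb$mother_id), ]
  p_f <- mean(born$sex == "female")
  expect_lt(abs(p_f - 0.5), 3 * sqrt(0.25 / nrow(born)))
  # offspring born strictly after parents, parents correctly sexed
  mo_by <- pedb$birth_year[match(born$mother_id, pedb$id)]
  expect_true(all(born$birth_year > mo_by))
  expect_true(all(pedb$sex[match(born$mother_id, pedb$id)] == "female"))
  expect_true(all(pedb$sex[match(born$father_id, pedb$id)] == "male"))
})

test_that("pedigree relatedness gives textbook values and matches the path oracle", {
  ped <- tibble::tibble(
    id = c("gm", "gf", "mo", "fa", "kid1", "kid2", "half"),
    sex = c("female", "male", "female", "male", "female", "male", "female"),
    mother_id = c(NA, NA, "gm", NA, "mo", "mo", "mo"),
    father_id = c(NA, NA, "gf", NA, "fa", "fa", NA),
    birth_year = c(0, 0, 1, 0, 2, 2, 3),
    population = "P1", dispersed_year = NA_integer_
  )
  class(ped) <- c("pedigree", class(ped))
  r <- pedigree_relatedness(ped)
  expect_equal(r["mo", "kid1"], 0.5)    # parent-offspring
  expect_equal(r["kid1", "kid2"], 0.5)  # full siblings
  expect_equal(r["kid1", "half"], 0.25) # half siblings
  expect_equal(r["gm", "kid1"], 0.25)   # grandparent
  expect_equal(r["fa", "half"], 0)      # unrelated
  expect_equal(r, kinship_path_oracle(ped))

  # random simulated pedigrees (<= 20 individuals), including inbreeding loops
  for (seed in 1:5) {
    cfg <- sim_config(n_founders = 6, n_years = 4, pup_rate = 0.8,
                      male_dispersal_prob = 0.3, seed = seed)
    pedr <- simulate_pedigree(cfg)
    pedr <- pedr[seq_len(min(nrow(pedr), 20)), ]
    class(pedr) <- c("pedigree", class(pedr))
    expect_equal(pedigree_relatedness(pedr), kinship_path_oracle(pedr),
                 info = paste("seed", seed))
  }

  # noise stays in [0,1], symmetric
  rn <- pedigree_relatedness(ped, noise_sd = 0.1)
  expect_true(all(rn >= 0 & rn <= 1))
  expect_true(isSymmetric(rn))
})

test_that("uniform group assembly when kin bias and partner preference are off", {
  cfg <- sim_config(n_founders = 12, n_years = 1, n_roosts = 4, groups_per_day = 3,
                    pup_rate = 0, days_per_year = 400, seed = 5)
  ped <- simulate_pedigree(cfg)
  truth <- simulate_roosting(ped, cfg)
  p1 <- truth[truth$population == "P1", ]
  # dyadic co-roosting frequency should be 1/G for every dyad
  days <- split(p1, p1$day)
  ids <- unique(p1$bat_id)
  co <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (d in days) {
    for (g in split(d$bat_id, d$group)) co[g, g] <- co[g, g] + 1
  }
  n_days <- length(days)
  off <- co[lower.tri(co)] / n_days
  expect_lt(abs(mean(off) - 1 / 3), 0.02)
  # chi-square goodness of fit on pooled same-group counts
  expected <- n_days / 3
  chi <- sum((co[lower.tri(co)] - expected)^2 / (expected * (1 - 1 / 3)))
  # ~ chisq with choose(6,2) df; very loose bound
  expect_lt(chi, 2.5 * choose(length(ids), 2))
})

test_that("partner preference alone raises social differentiation without kin bias", {
  base <- list(n_founders = 16, n_years = 2, n_roosts = 4, groups_per_day = 3,
               pup_rate = 0, days_per_year = 60)
  truth_cv <- function(pi_w, seed) {
    cfg <- do.call(sim_config, c(base, list(partner_preference = pi_w, seed = seed)))
    ped <- simulate_pedigree(cfg)
    truth <- simulate_roosting(ped, cfg)
    p1 <- truth[truth$population == "P1", ]
    ids <- unique(p1$bat_id)
    co <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (d in split(p1, interaction(p1$year, p1$day, drop = TRUE))) {
      for (g in split(d$bat_id, d$group)) co[g, g] <- co[g, g] + 1
    }
    v <- co[lower.tri(co)]
    sd(v) / mean(v)
  }
  cv_pref <- mean(vapply(1:3, function(s) truth_cv(6, s), numeric(1)))
  cv_null <- mean(vapply(1:3, function(s) truth_cv(0, s + 10), numeric(1)))
  expect_gt(cv_pref, cv_null * 1.3)
})

test_that("one group per population makes everyone co-roost (SRI = 1)", {
  cfg <- sim_config(n_founders = 8, n_years = 1, n_roosts = 1, groups_per_day = 1,
                    pup_rate = 0, days_per_year = 10, captures_per_year = 5,
                    detection_prob = 1, roost_switch_prob = 0, seed = 6)
  sim <- simulate_colony(cfg)
  a <- simple_ratio_index(build_gbi(filter_captures(sim$dataset, min_sightings = 1)))
  within <- outer(a$bats$population, a$bats$population, "==") & lower.tri(a$sri)
  expect_true(all(a$sri[within] == 1))
})

test_that("capture sampling respects detection probability and round-trips", {
  cfg1 <- sim_config(n_founders = 16, n_years = 2, captures_per_year = 15,
                     days_per_year = 20, detection_prob = 1, seed = 7)
  sim1 <- simulate_colony(cfg1)
  occ <- attr(sim1$dataset, "occasions")
  # perfect detection: every event equals the full true group at that roost
  ev <- sim1$dataset$events
  for (i in sample(nrow(ev), min(10, nrow(ev)))) {
    e <- ev[i, ]
    members <- sim1$dataset$captures$bat_id[sim1$dataset$captures$event_id == e$event_id]
    yr <- e$year - cfg1$base_year + 1
    day <- as.integer(e$date - as.Date(sprintf("%d-01-01", e$year))) /
      max(1, floor(364 / cfg1$days_per_year)) + 1
    true_members <- sim1$truth$bat_id[sim1$truth$year == yr &
                                        sim1$truth$day == day &
                                        sim1$truth$roost_id == e$roost_id]
    expect_setequal(members, true_members)
  }

  # detection 0.5: mean recorded size ~ half the true size
  cfg2 <- sim_config(n_founders = 40, n_years = 2, captures_per_year = 40,
                     days_per_year = 30, detection_prob = 0.5, seed = 8)
  sim_full <- simulate_colony(sim_config(n_founders = 40, n_years = 2,
                                         captures_per_year = 40, days_per_year = 30,
                                         detection_prob = 1, seed = 8))
  sim_half <- simulate_colony(cfg2)
  ratio <- sum(sim_half$dataset$events$size) / sum(sim_full$dataset$events$size)
  expect_lt(abs(ratio - 0.5), 0.08)

  # round trip through the captures dialect
  path <- withr::local_tempfile(fileext = ".csv")
  write_captures(sim1$dataset, path)
  ds2 <- read_captures(path, quiet = TRUE)
  expect_equal(dplyr::arrange(ds2$captures, bat_id, date, roost_id),
               dplyr::arrange(sim1$dataset$captures, bat_id, date, roost_id))
})

test_that("female philopatry leaves the expected recapture signature", {
  cfg <- sim_config(n_founders = 60, n_years = 6, captures_per_year = 40,
                    days_per_year = 30, pup_rate = 0.7,
                    male_dispersal_prob = 0.9, seed = 9)
  sim <- simulate_colony(cfg)
  spans <- juvenile_recapture_spans(sim$dataset)
  expect_true(all(c("female", "male") %in% spans$sex))
  v_f <- var(spans$span_days[spans$sex == "female"])
  v_m <- var(spans$span_days[spans$sex == "male"])
  expect_gt(v_f, v_m)
})
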