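#' Analysis configuration
#'
#' Declarative configuration for [run_analysis()]. All defaults mirror the
#' package's canonical analysis: adults only, bats captured at least four
#' times for the association analyses (with the all-adults variant also
#' reported), 5000 datastream null networks, 10000/5000 permutations for the
#' univariate mean/variance tests, 5000 Mantel permutations and 5000 draws for
#' the two-male relatedness null. A yaml file with these keys can be passed to
#' [run_analysis()] directly.
#'
#' @param captures Path to a captures CSV or a `capture_dataset`.
#' @param roosts Path to a roosts CSV or a registry tibble (optional if
#'   `captures` is a dataset that already carries one).
#' @param relatedness Path to a relatedness CSV or a symmetric matrix.
#' @param min_sightings Sighting threshold for the association subset.
#' @param adults_only Restrict social analyses to adults.
#' @param n_networks,swaps_per_sample,burn_in_swaps Datastream permutation
#'   settings (see [perm_config()]).
#' @param n_perm_mean,n_perm_var,n_perm_mantel,n_draws Permutation counts for
#'   the univariate mean-difference and variance-ratio tests, the Mantel
#'   tests, and the two-male relatedness null.
#' @param period Sampling-period convention for the simple ratio index.
#' @param mantel_bats Optional explicit bat list for the Mantel tests
#'   (defaults to all genotyped adults).
#' @param seed Master seed; every reported p-value is reproducible from it.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(captures, roosts = NULL, relatedness = NULL,
                            min_sightings = 4, adults_only = TRUE,
                            n_networks = 5000, swaps_per_sample = 100,
                            burn_in_swaps = 1000, n_perm_mean = 10000,
                            n_perm_var = 5000, n_perm_mantel = 5000,
                            n_draws = 5000, period = "date-population",
                            mantel_bats = NULL, seed = 1) {
  structure(mget(names(formals())), class = "analysis_config")
}

load_analysis_inputs <- function(config) {
  roosts <- config$roosts
  if (is.character(roosts)) roosts <- read_roosts(roosts)
  ds <- config$captures
  if (is.character(ds)) ds <- read_captures(ds, roosts = roosts, quiet = TRUE)
  if (!inherits(ds, "capture_dataset")) stop("captures must be a path or a capture_dataset")
  if (is.null(ds$roosts) && !is.null(roosts)) ds$roosts <- roosts
  rel <- config$relatedness
  if (is.character(rel)) rel <- read_relatedness(rel)
  list(ds = ds, relatedness = rel)
}

#' Run the full social-structure analysis
#'
#' Executes, with stage-level logging of record counts: descriptive summaries
#' (bats, group captures, group sizes and composition, sightings-threshold
#' curve); the philopatry variance-ratio test on juvenile-to-adult recapture
#' spans (orientation: males/females, so female philopatry gives F < 1); sex
#' comparisons of roost use (roosts used, switch rate, mean distance between
#' used roosts); social differentiation (CV of the simple ratio index) with
#' datastream-permutation p-values for the all/female/male dyad sets at both
#' the sighting-threshold and all-adults settings; the kin-bias Mantel/QAP
#' suite; and the two-male within-group relatedness null. Every p-value in
#' the report carries its permutation count and the master seed.
#'
#' @param config An [analysis_config()], a list of its fields, or a path to a
#'   yaml file with them.
#' @param quiet Suppress stage messages.
#' @return An object of class `roost_report`: list with `descriptives`,
#'   `composition`, `sightings_curve`, `roost_use`, `tests` (tidy table),
#'   `two_male`, `config`.
#' @export
run_analysis <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "analysis_config")) {
    config <- do.call(analysis_config, config)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  set.seed(config$seed)

  inputs <- stage("load", load_analysis_inputs(config))
  ds <- inputs$ds
  relatedness <- inputs$relatedness
  say("loaded %d records, %d bats, %d events",
      nrow(ds$captures), dplyr::n_distinct(ds$captures$bat_id), nrow(ds$events))

  desc <- glance(ds)
  comp <- group_composition(ds)
  comp_counts <- comp |> dplyr::count(.data$class)

  ds_adults <- stage("filter", filter_captures(ds, adults_only = config$adults_only,
                                               min_sightings = 1))
  ds_min <- stage("filter", filter_captures(ds, adults_only = config$adults_only,
                                            min_sightings = config$min_sightings))
  say("filter attrition: %d bats -> %d adults -> %d seen >= %d times",
      desc$n_bats, dplyr::n_distinct(ds_adults$captures$bat_id),
      dplyr::n_distinct(ds_min$captures$bat_id), config$min_sightings)
  curve <- sightings_threshold_curve(ds_adults)

  tests <- list()
  add_test <- function(test, subset, row) {
    tests[[length(tests) + 1]] <<- dplyr::bind_cols(
      tibble::tibble(test = test, subset = subset), row)
  }

  # --- philopatry: juvenile-to-adult span variance, males/females
  spans <- juvenile_recapture_spans(ds)
  say("philopatry: %d bats captured as juveniles and recaptured as adults", nrow(spans))
  if (all(c("male", "female") %in% spans$sex) &&
      all(table(factor(spans$sex, c("male", "female"))) >= 2)) {
    ft <- stage("philopatry", permuted_variance_ratio_test(
      spans$span_days, factor(spans$sex, levels = c("male", "female")),
      n_perm = config$n_perm_var))
    add_test("philopatry_span_variance", "male/female", tidy(ft))
  } else {
    say("philopatry test skipped: too few recaptured juveniles per sex")
  }

  # --- roost use by sex (well-sampled bats)
  use <- stage("roost_use", roost_use_summaries(ds_min))
  if (nrow(use) > 0 && dplyr::n_distinct(use$sex) == 2) {
    sexf <- factor(use$sex, levels = c("male", "female"))
    add_test("roost_count_by_sex", "male-female",
             tidy(permuted_mean_diff_test(use$n_roosts_used, sexf,
                                          n_perm = config$n_perm_mean)))
    add_test("roost_switch_rate_by_sex", "male-female",
             tidy(permuted_mean_diff_test(use$switch_rate, sexf,
                                          n_perm = config$n_perm_mean)))
    if (!all(is.na(use$mean_roost_distance_m))) {
      add_test("roost_distance_by_sex", "male-female",
               tidy(permuted_mean_diff_test(use$mean_roost_distance_m, sexf,
                                            n_perm = config$n_perm_mean)))
    }
  }

  # --- social differentiation at both sighting thresholds
  pc <- perm_config(n_networks = config$n_networks,
                    swaps_per_sample = config$swaps_per_sample,
                    burn_in_swaps = config$burn_in_swaps)
  for (setting in list(list(ds = ds_min, label = sprintf("min%d", config$min_sightings)),
                       list(ds = ds_adults, label = "all-adults"))) {
    dsx <- setting$ds
    if (dplyr::n_distinct(dsx$captures$bat_id) < 3) next
    gbi <- stage("association", build_gbi(dsx))
    assoc <- simple_ratio_index(gbi, period = config$period)
    masks <- list(all = NULL,
                  female = dyad_mask(assoc, sex = "female"),
                  male = dyad_mask(assoc, sex = "male"))
    cv_fun <- function(a, g) {
      vapply(masks, function(m) suppressWarnings(social_differentiation(a, m)),
             numeric(1))
    }
    obs_cv <- cv_fun(assoc, gbi)
    say("social differentiation [%s]: CV(all) = %.3f over %d bats",
        setting$label, obs_cv[["all"]], nrow(gbi$bats))
    nulls <- stage("null_networks", generate_null_networks(gbi, pc, fun = cv_fun,
                                                           period = config$period))
    null_mat <- do.call(rbind, nulls)
    for (nm in names(masks)) {
      nb <- null_mat[, nm]
      nb <- nb[!is.na(nb)]
      if (is.na(obs_cv[[nm]]) || length(nb) == 0) next
      ep <- empirical_p(obs_cv[[nm]], nb)
      n_b <- switch(nm, all = nrow(gbi$bats),
                    sum(gbi$bats$sex == nm))
      add_test("social_differentiation", paste(setting$label, nm, sep = "/"),
               tibble::tibble(statistic_name = "cv_sri", statistic = obs_cv[[nm]],
                              n_1 = n_b, p_value = ep$p_value,
                              p_display = ep$p_display, n_perm = length(nb)))
    }
  }

  # --- kin bias suite on the well-sampled subset
  two_male <- NULL
  if (!is.null(relatedness)) {
    if (dplyr::n_distinct(ds_min$captures$bat_id) >= 3) {
      gbi_min <- build_gbi(ds_min)
      adult_sexes <- ds_adults$captures |>
        dplyr::distinct(.data$bat_id, .data$sex)
      sexes <- setNames(adult_sexes$sex, adult_sexes$bat_id)
      kb <- stage("kin_bias", kin_bias_suite(
        gbi_min, relatedness, config = pc,
        mantel_bats = config$mantel_bats,
        sexes = sexes,
        mantel_n_perm = config$n_perm_mantel, period = config$period))
      tests[[length(tests) + 1]] <- kb |>
        dplyr::rename(n_1 = "n_bats", n_perm = "n_null") |>
        dplyr::mutate(test = paste0("kin_bias/", .data$test))
    }
    two_male <- tryCatch(
      stage("two_male", two_male_relatedness_null(ds, relatedness,
                                                  n_draws = config$n_draws)),
      error = function(e) {
        say("two-male relatedness null skipped: %s", conditionMessage(e))
        NULL
      })
  }

  tests_tbl <- dplyr::bind_rows(tests) |>
    dplyr::mutate(seed = config$seed)
  out <- structure(list(descriptives = desc, composition = comp_counts,
                        sightings_curve = curve, roost_use = use,
                        spans = spans, tests = tests_tbl, two_male = two_male,
                        config = config),
                   class = "roost_report")
  out
}

#' @export
print.roost_report <- function(x, ...) {
  d <- x$descriptives
  cat(sprintf("<roost_report> %d bats | %d group captures | %d observations\n",
              d$n_bats, d$n_events, d$n_records))
  cat(sprintf("  median group size %s | composition: %s\n", d$median_group_size,
              paste(sprintf("%s=%d", x$composition$class, x$composition$n),
                    collapse = ", ")))
  print(as.data.frame(x$tests[, c("test", "subset", "statistic_name",
                                  "statistic", "p_display", "n_perm")]),
        row.names = FALSE)
  if (!is.null(x$two_male)) print(x$two_male)
  invisible(x)
}

#' Write an analysis report bundle
#'
#' `report.csv` holds the tidy test table; `report.md` a human-readable
#' summary; `config.json` the full configuration echo (provenance: every
#' setting, the seed, and each test's permutation count are recoverable).
#'
#' @param report A `roost_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$tests, file.path(dir, "report.csv"), na = "")
  cfg <- report$config
  cfg$captures <- if (is.character(cfg$captures)) cfg$captures else "<in-memory>"
  cfg$roosts <- if (is.character(cfg$roosts)) cfg$roosts else "<in-memory>"
  cfg$relatedness <- if (is.character(cfg$relatedness)) cfg$relatedness else "<in-memory>"
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  md <- c(
    "# Roost social-structure report", "",
    sprintf("- bats: %d; group captures: %d; observations: %d",
            report$descriptives$n_bats, report$descriptives$n_events,
            report$descriptives$n_records),
    sprintf("- median group size: %s", report$descriptives$median_group_size),
    sprintf("- group composition: %s",
            paste(sprintf("%s = %d", report$composition$class, report$composition$n),
                  collapse = ", ")),
    "",
    "## Tests", "",
    knitr_like_table(report$tests[, c("test", "subset", "statistic", "p_display",
                                      "n_perm")]),
    "",
    if (!is.null(report$two_male)) {
      sprintf("Two-male relatedness: observed %.3f, null 95%% CI [%.3f, %.3f] (%d draws)",
              report$two_male$observed_mean, report$two_male$ci[1],
              report$two_male$ci[2], report$two_male$n_draws)
    } else "",
    "",
    sprintf("Seed: %s. Null networks per CV/QAP test and permutation counts are in report.csv.",
            report$config$seed)
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

# Minimal pipe-table rendering without extra dependencies.
knitr_like_table <- function(df) {
  df <- as.data.frame(df)
  df[] <- lapply(df, function(v) if (is.numeric(v)) sprintf("%.4g", v) else as.character(v))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Run the simulator from a declarative config
#'
#' Wraps [simulate_colony()] and [write_simulation()]: builds the
#' [sim_config()] from a list or yaml file, simulates, optionally writes the
#' bundle.
#'
#' @param config A `sim_config`, a list of its fields, or a yaml path.
#' @param output_dir Optional directory for the dataset bundle.
#' @return The `roost_simulation`, invisibly when writing.
#' @export
run_simulation <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  sim <- simulate_colony(config)
  if (nrow(sim$dataset$captures) == 0) {
    warning("simulation produced no capture records (n_years = 0 or extinction)")
  }
  if (!is.null(output_dir)) {
    write_simulation(sim, output_dir)
    return(invisible(sim))
  }
  sim
}
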