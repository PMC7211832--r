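test_that("capture events are derived by grouping on (date, roost)", {
  rows <- dplyr::bind_rows(
    capture_row("A", "2015-06-01", "r1"),
    capture_row("B", "2015-06-01", "r1", sex = "male"),
    capture_row("A", "2015-06-02", "r1")
  )
  ds <- as_capture_dataset(rows)
  expect_equal(nrow(ds$events), 2)
  expect_equal(sort(ds$events$size), c(1, 2))
  # same roost, different date -> distinct events
  expect_equal(dplyr::n_distinct(ds$captures$event_id), 2)
})

test_that("a bat duplicated within one event is rejected by name", {
  rows <- dplyr::bind_rows(
    capture_row("A", "2015-06-01", "r1"),
    capture_row("A", "2015-06-01", "r1")
  )
  expect_error(as_capture_dataset(rows), "A at r1")
})

test_that("unknown codes and unresolved roosts are rejected with row context", {
  base <- capture_row("A", "2015-06-01", "r1")
  expect_error(as_capture_dataset(dplyr::mutate(base, sex = "f")), "unknown sex")
  expect_error(as_capture_dataset(dplyr::mutate(base, age_class = "pup")), "age_class")
  expect_error(as_capture_dataset(dplyr::mutate(base, date = "June 1")), "date")
  reg <- tibble::tibble(roost_id = "r9", population = "P1", x = 0, y = 0)
  attr(reg, "coord_system") <- "planar"
  expect_error(as_capture_dataset(base, roosts = reg), "unknown roost_id")
})

test_that("write/read round-trip reproduces records and events exactly", {
  ds <- random_small_ds(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_captures(ds, path)
  ds2 <- read_captures(path, quiet = TRUE)
  ord <- function(x) dplyr::arrange(x$captures, bat_id, date, roost_id)
  expect_equal(ord(ds2), ord(ds))
  expect_equal(ds2$events, ds$events)
})

test_that("event derivation is invariant to record order", {
  ds <- random_small_ds(seed = 11)
  shuffled <- ds$captures[sample(nrow(ds$captures)), ]
  ds2 <- as_capture_dataset(dplyr::select(shuffled, -"event_id", -"year"))
  expect_equal(ds2$events, ds$events)
})

test_that("filtering is idempotent and counts sightings on the restricted set", {
  set.seed(21)
  ds <- random_small_ds(seed = 21, n_bats = 6, n_events = 12)
  f1 <- filter_captures(ds, adults_only = TRUE, min_sightings = 3)
  f2 <- filter_captures(f1, adults_only = TRUE, min_sightings = 3)
  expect_equal(f2$captures, f1$captures)
  expect_equal(f2$events, f1$events)

  # brute-force recount: every retained bat has >= 3 events in the output
  tally <- f1$captures |>
    dplyr::distinct(bat_id, date, roost_id) |>
    dplyr::count(bat_id)
  expect_true(all(tally$n >= 3))
  # and no excluded adult bat had >= 3 sightings
  full_tally <- ds$captures |>
    dplyr::filter(age_class == "adult") |>
    dplyr::distinct(bat_id, date, roost_id) |>
    dplyr::count(bat_id)
  excluded <- setdiff(full_tally$bat_id, tally$bat_id)
  expect_true(all(full_tally$n[full_tally$bat_id %in% excluded] < 3))
})

test_that("min_sightings = 1 equals the adults filter alone", {
  ds <- random_small_ds(seed = 5)
  a <- filter_captures(ds, adults_only = TRUE, min_sightings = 1)
  b <- filter_captures(ds, adults_only = TRUE)
  expect_equal(a$captures, b$captures)
})

test_that("sightings threshold curve matches direct tallies and is monotone", {
  rows <- dplyr::bind_rows(
    capture_row("A", "2015-06-01", "r1"),
    capture_row("A", "2015-06-02", "r1"),
    capture_row("A", "2015-06-03", "r2"),
    capture_row("B", "2015-06-01", "r1"),
    capture_row("C", "2015-06-02", "r1")
  )
  curve <- sightings_threshold_curve(as_capture_dataset(rows))
  expect_equal(curve$n_bats, c(3, 1, 1))   # counts {3,1,1}

  ds <- random_small_ds(seed = 9)
  curve <- sightings_threshold_curve(ds)
  expect_equal(curve$n_bats[1], dplyr::n_distinct(ds$captures$bat_id))
  expect_true(all(diff(curve$n_bats) <= 0))
  tally <- table(ds$captures$bat_id)
  expect_equal(curve$n_bats,
               vapply(curve$n_min, function(k) sum(tally >= k), integer(1)))
})

test_that("group composition classifies events from sex alone", {
  rows <- dplyr::bind_rows(
    capture_row("A", "2015-06-01", "r1", sex = "female"),
    capture_row("B", "2015-06-01", "r1", sex = "female"),
    capture_row("C", "2015-06-01", "r1", sex = "male"),
    capture_row("D", "2015-06-02", "r1", sex = "male", repro = "scrotal")
  )
  comp <- group_composition(as_capture_dataset(rows))
  expect_equal(comp$class, c("mixed", "all-male"))
  expect_equal(comp$size, c(3, 1))
  expect_equal(comp$n_reproductive_males, c(0, 1))
  expect_setequal(unique(comp$class) , c("mixed", "all-male"))
})

test_that("composition classes match the simulator's ground truth", {
  cfg <- sim_config(n_founders = 16, n_years = 2, n_roosts = 4, groups_per_day = 2,
                    captures_per_year = 12, days_per_year = 20,
                    detection_prob = 1, seed = 77)
  sim <- simulate_colony(cfg)
  comp <- group_composition(sim$dataset)
  sex_of <- setNames(sim$pedigree$sex, sim$pedigree$id)
  # with perfect detection each event is exactly the true roost group
  truth_class <- comp |>
    dplyr::left_join(sim$dataset$captures |>
                       dplyr::group_by(event_id) |>
                       dplyr::summarise(members = list(bat_id)),
                     by = "event_id") |>
    dplyr::mutate(expected = purrr::map_chr(members, function(m) {
      sx <- sex_of[m]
      if (all(sx == "male")) "all-male" else if (all(sx == "female")) "all-female" else "mixed"
    }))
  expect_equal(truth_class$class, truth_class$expected)
})

test_that("roost registry round-trips and distances respect the coordinate system", {
  reg <- tibble::tibble(roost_id = c("r1", "r2"), population = "P1",
                        x = c(0, 300), y = c(0, 400))
  attr(reg, "coord_system") <- "planar"
  path <- withr::local_tempfile(fileext = ".csv")
  write_roosts(reg, path)
  reg2 <- read_roosts(path)
  expect_equal(attr(reg2, "coord_system"), "planar")
  d <- roost_distances(reg2)
  expect_equal(unname(d["r1", "r2"]), 500)    # 3-4-5 triangle
  expect_true(isSymmetric(d))

  geo <- tibble::tibble(roost_id = c("g1", "g2"), population = "P1",
                        x = c(-79.66, -79.66), y = c(9.07, 9.08))
  attr(geo, "coord_system") <- "geographic"
  dg <- roost_distances(geo)
  # 0.01 degree of latitude is ~1.11 km
  expect_equal(unname(dg["g1", "g2"]), 1112, tolerance = 0.01)

  writeLines(c("roost_id,population,x,y", "r1,P1,0,0"), path)
  expect_error(read_roosts(path), "coordinate-system header")
})

test_that("relatedness matrices round-trip with missing cells and reject asymmetry", {
  r <- matrix(c(1, 0.5, NA, 0.5, 1, 0.25, NA, 0.25, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_relatedness(r, path)
  r2 <- read_relatedness(path)
  expect_equal(r2, r)

  bad <- r
  bad[2, 1] <- 0.9
  write_square_matrix <- getFromNamespace("write_square_matrix", "roostnet")
  write_square_matrix(bad, path)
  expect_error(read_relatedness(path), "not symmetric")
})
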