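#' Read a roost registry
#'
#' The registry CSV begins with a header line declaring the coordinate system,
#' `# coordinates: planar` (x, y in metres; Euclidean distances) or
#' `# coordinates: geographic` (lon, lat in decimal degrees; great-circle
#' distances), followed by columns `roost_id,population,x,y`.
#'
#' @param path Path to a roosts CSV.
#' @return A tibble with columns `roost_id`, `population`, `x`, `y` and
#'   attribute `coord_system`.
#' @export
read_roosts <- function(path) {
  first <- readLines(path, n = 1)
  m <- regmatches(first, regexec("^#\\s*coordinates:\\s*(planar|geographic)\\s*$", first))[[1]]
  if (length(m) < 2) {
    stop("roost registry must start with a coordinate-system header line, ",
         "'# coordinates: planar' or '# coordinates: geographic'; got: ",
         first, call. = FALSE)
  }
  coord <- m[2]
  roosts <- readr::read_csv(path, skip = 1, col_types = readr::cols(
    roost_id = readr::col_character(),
    population = readr::col_character(),
    x = readr::col_double(),
    y = readr::col_double()
  ))
  missing_cols <- setdiff(c("roost_id", "population", "x", "y"), names(roosts))
  if (length(missing_cols) > 0) {
    stop("roost registry is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(roosts$roost_id)) {
    stop("duplicated roost_id in registry: ",
         paste(unique(roosts$roost_id[duplicated(roosts$roost_id)]), collapse = ", "),
         call. = FALSE)
  }
  attr(roosts, "coord_system") <- coord
  roosts
}

#' Write a roost registry
#'
#' @param roosts Tibble with `roost_id`, `population`, `x`, `y` and attribute
#'   `coord_system` (`"planar"` unless set).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roosts <- function(roosts, path) {
  coord <- attr(roosts, "coord_system") %||% "planar"
  writeLines(sprintf("# coordinates: %s", coord), path)
  readr::write_csv(roosts[, c("roost_id", "population", "x", "y")], path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Pairwise distances between roosts, in metres
#'
#' Euclidean for planar registries, great-circle (haversine) for geographic
#' ones. The result is a symmetric nonnegative matrix keyed by `roost_id`.
#'
#' @param roosts A roost registry from [read_roosts()].
#' @return A symmetric numeric matrix of distances in metres.
#' @export
roost_distances <- function(roosts) {
  coord <- attr(roosts, "coord_system") %||% "planar"
  ids <- roosts$roost_id
  if (coord == "geographic") {
    d <- geosphere::distm(as.matrix(roosts[, c("x", "y")]),
                          fun = geosphere::distHaversine)
  } else {
    d <- as.matrix(stats::dist(as.matrix(roosts[, c("x", "y")])))
  }
  dimnames(d) <- list(ids, ids)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
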