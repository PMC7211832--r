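#' Read a dyadic relatedness matrix
#'
#' Square CSV with a bat-id header row and a leading bat-id column; empty
#' cells are missing (ungenotyped dyads). Values must lie in [0, 1] and the
#' matrix must be symmetric; the diagonal is ignored by every analysis.
#'
#' @param path Path to a relatedness CSV.
#' @return A symmetric numeric matrix with bat ids as dimnames.
#' @export
read_relatedness <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_double(), bat_id = readr::col_character()))
  if (!"bat_id" %in% names(raw)) {
    stop("relatedness file must have a leading 'bat_id' column", call. = FALSE)
  }
  ids <- raw$bat_id
  r <- as.matrix(raw[, setdiff(names(raw), "bat_id")])
  if (!identical(colnames(r), ids)) {
    stop("relatedness header row and bat_id column disagree", call. = FALSE)
  }
  rownames(r) <- ids
  validate_relatedness(r)
  r
}

validate_relatedness <- function(r) {
  if (nrow(r) != ncol(r)) stop("relatedness matrix must be square", call. = FALSE)
  off <- r[lower.tri(r)]
  if (any(off < 0 | off > 1, na.rm = TRUE)) {
    stop("relatedness values must lie in [0, 1]", call. = FALSE)
  }
  ut <- t(r)[lower.tri(r)]
  same <- is.na(off) == is.na(ut) & (is.na(off) | abs(off - ut) < 1e-8)
  if (!all(same)) stop("relatedness matrix is not symmetric", call. = FALSE)
  invisible(r)
}

#' Write a dyadic relatedness (or association) matrix
#'
#' Emits the square-matrix CSV dialect read by [read_relatedness()]: a
#' `bat_id` header column, bat ids as remaining column names, empty cells for
#' missing values.
#'
#' @param r A symmetric numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relatedness <- function(r, path) {
  write_square_matrix(r, path)
}

# Square-matrix CSV writer shared by the relatedness and association dialects.
write_square_matrix <- function(r, path) {
  df <- tibble::as_tibble(r, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(bat_id = rownames(r)), df)
  readr::write_csv(df, path, na = "")
  invisible(path)
}
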