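#' Mantel test of two dyadic matrices
#'
#' Pearson correlation of the vectorized lower triangles over defined dyads
#' (positions finite in both matrices), with significance from joint
#' row/column label permutations of the second matrix. P-values follow the
#' two-sided-doubled convention of [empirical_p()] by default.
#'
#' @param A,B Symmetric numeric matrices over the same bats in the same order
#'   (an `assoc_matrix` is accepted for either).
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Optional integer seed.
#' @param alternative Passed to [empirical_p()].
#' @return An object of class `mantel_result`: `r`, `p_value`, `p_display`,
#'   `n_bats`, `n_dyads`, `n_perm`, `null_r`.
#' @export
mantel_test <- function(A, B, n_perm = 5000, seed = NULL,
                        alternative = "two-sided-doubled") {
  A <- as_dyadic_matrix(A)
  B <- as_dyadic_matrix(B)
  stopifnot(nrow(A) == ncol(A), identical(dim(A), dim(B)))
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop("matrices are not over the same bats in the same order", call. = FALSE)
  }
  n <- nrow(A)
  if (n < 3) stop("Mantel test requires at least 3 bats", call. = FALSE)
  mask <- lower.tri(A) & is.finite(A) & is.finite(B)
  if (sum(mask) < 3) stop("fewer than 3 defined dyads", call. = FALSE)
  va <- A[mask]
  vb <- B[mask]
  if (sd(va) == 0 || sd(vb) == 0) {
    warning("zero variance over defined dyads; Mantel r undefined")
    return(structure(list(r = NA_real_, p_value = NA_real_, p_display = NA_character_,
                          n_bats = n, n_dyads = sum(mask), n_perm = 0,
                          null_r = numeric(0)),
                     class = "mantel_result"))
  }
  r <- cor(va, vb)
  if (!is.null(seed)) set.seed(seed)
  null_r <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    Bp <- B[idx, idx]
    vbp <- Bp[mask]
    ok <- is.finite(vbp)
    if (sum(ok) < 3 || sd(vbp[ok]) == 0) return(NA_real_)
    cor(va[ok], vbp[ok])
  }, numeric(1))
  null_r <- null_r[!is.na(null_r)]
  ep <- empirical_p(r, null_r, alternative = alternative)
  structure(list(r = r, p_value = ep$p_value, p_display = ep$p_display,
                 n_bats = n, n_dyads = sum(mask), n_perm = length(null_r),
                 null_r = null_r),
            class = "mantel_result")
}

as_dyadic_matrix <- function(x) {
  if (inherits(x, "assoc_matrix")) x$sri else as.matrix(x)
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.3f, n = %d bats (%d dyads), p %s [%d permutations]\n",
              x$r, x$n_bats, x$n_dyads,
              if (is.na(x$p_value)) "NA" else x$p_display, x$n_perm))
  invisible(x)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(statistic = x$r, p_value = x$p_value, p_display = x$p_display,
                 n_bats = x$n_bats, n_dyads = x$n_dyads, n_null = x$n_perm)
}

#' Binary dyad-type predictor matrix
#'
#' Encodes the presence of one dyad type: `B[a, b] = 1` iff the dyad matches
#' `type`. Over fully sexed bats the three type matrices partition all dyads.
#'
#' @param sexes Named character vector mapping bat id to `"female"`/`"male"`.
#' @param type One of `"female-female"`, `"male-male"`, `"female-male"`.
#' @return A symmetric 0/1 matrix with attribute `dyad_type`.
#' @export
dyad_type_matrix <- function(sexes, type = c("female-female", "male-male", "female-male")) {
  type <- match.arg(type)
  bad <- !sexes %in% c("female", "male")
  if (any(bad)) {
    stop("unknown sex for bat(s): ", paste(names(sexes)[bad], collapse = ", "),
         call. = FALSE)
  }
  f <- sexes == "female"
  B <- switch(type,
              `female-female` = outer(f, f, "&"),
              `male-male` = outer(!f, !f, "&"),
              `female-male` = outer(f, f, "!="))
  B <- B * 1
  dimnames(B) <- list(names(sexes), names(sexes))
  diag(B) <- 0
  attr(B, "dyad_type") <- type
  B
}

#' QAP regression of a dyadic response on dyadic predictors
#'
#' Ordinary least squares over the vectorized defined lower-triangle dyads
#' (intercept included), with per-coefficient empirical p-values from one of
#' two null distributions: `"node-permutation"` (re-fit after jointly
#' permuting rows and columns of the response) or `"custom"` (re-fit with each
#' supplied pre-network-permuted association matrix as the response against
#' the unpermuted predictors).
#'
#' @param response An `assoc_matrix` or symmetric numeric matrix.
#' @param predictors A symmetric matrix or named list of symmetric matrices.
#' @param null `"node-permutation"` or `"custom"`.
#' @param n_perm Number of node permutations (when `null = "node-permutation"`).
#' @param null_networks List of null association matrices (when
#'   `null = "custom"`), e.g. from [generate_null_networks()].
#' @param bats Optional bat ids to subset all matrices to before building
#'   dyads (sex-subset analyses).
#' @param standardize Z-score response and predictors over the defined dyads
#'   before fitting (default FALSE: raw-scale coefficients).
#' @param seed Optional integer seed (node permutations).
#' @param alternative Passed to [empirical_p()].
#' @return An object of class `qap_result`: tibble `coefficients`
#'   (term, beta, p_value, p_display), matrix `null_betas`, `n_bats`,
#'   `n_dyads`, `null_source`, `n_null`.
#' @export
qap_regression <- function(response, predictors,
                           null = c("node-permutation", "custom"),
                           n_perm = 1000, null_networks = NULL, bats = NULL,
                           standardize = FALSE, seed = NULL,
                           alternative = "two-sided-doubled") {
  null <- match.arg(null)
  Y <- as_dyadic_matrix(response)
  if (is.matrix(predictors)) predictors <- list(predictor = predictors)
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    names(predictors) <- paste0("x", seq_along(predictors))
  }
  preds <- lapply(predictors, as_dyadic_matrix)

  if (!is.null(bats)) {
    idx <- intersect(rownames(Y), bats)
    if (length(idx) < 3) stop("fewer than 3 bats after subsetting", call. = FALSE)
    Y <- Y[idx, idx]
    preds <- lapply(preds, function(P) P[idx, idx])
  }
  n <- nrow(Y)
  mask <- lower.tri(Y) & is.finite(Y)
  for (P in preds) {
    stopifnot(identical(dim(P), dim(Y)))
    mask <- mask & is.finite(P)
  }
  if (sum(mask) <= length(preds) + 1) stop("too few defined dyads to fit", call. = FALSE)

  y <- Y[mask]
  X <- cbind(`(Intercept)` = 1, vapply(preds, function(P) P[mask], numeric(sum(mask))))
  if (standardize) {
    y <- as.numeric(scale(y))
    X[, -1] <- apply(X[, -1, drop = FALSE], 2, function(v) as.numeric(scale(v)))
  }
  zero_var <- apply(X[, -1, drop = FALSE], 2, function(v) sd(v) == 0)
  if (any(zero_var)) {
    stop("predictor(s) constant over the defined dyads: ",
         paste(names(preds)[zero_var], collapse = ", "), call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[(qx$rank + 1):ncol(X)]
    stop("collinear predictor matrices: ",
         paste(colnames(X)[drop_idx], collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)

  refit <- function(ynew) qr.coef(qx, ynew)
  if (null == "node-permutation") {
    if (!is.null(seed)) set.seed(seed)
    null_betas <- t(vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      Yp <- Y[idx, idx]
      refit(Yp[mask])
    }, numeric(ncol(X))))
  } else {
    if (is.null(null_networks) || length(null_networks) == 0) {
      stop("null = 'custom' requires a non-empty list of null association matrices",
           call. = FALSE)
    }
    null_betas <- t(vapply(null_networks, function(a) {
      Yk <- as_dyadic_matrix(a)
      if (!is.null(bats)) Yk <- Yk[rownames(Y), rownames(Y)]
      yk <- Yk[mask]
      if (standardize) yk <- as.numeric(scale(yk))
      refit(yk)
    }, numeric(ncol(X))))
  }
  colnames(null_betas) <- colnames(X)

  coefs <- purrr::map_dfr(seq_along(beta), function(j) {
    ep <- empirical_p(beta[j], null_betas[, j], alternative = alternative)
    tibble::tibble(term = colnames(X)[j], beta = unname(beta[j]),
                   p_value = ep$p_value, p_display = ep$p_display)
  })
  structure(list(coefficients = coefs, null_betas = null_betas,
                 n_bats = n, n_dyads = sum(mask),
                 null_source = null, n_null = nrow(null_betas)),
            class = "qap_result")
}

#' @export
print.qap_result <- function(x, ...) {
  cat(sprintf("QAP regression (%s nulls, %d): n = %d bats, %d dyads\n",
              x$null_source, x$n_null, x$n_bats, x$n_dyads))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.qap_result <- function(x, ...) {
  x$coefficients |>
    dplyr::rename(estimate = "beta") |>
    dplyr::mutate(n_bats = x$n_bats, n_null = x$n_null,
                  null_source = x$null_source)
}

#' @export
glance.qap_result <- function(x, ...) {
  tibble::tibble(n_bats = x$n_bats, n_dyads = x$n_dyads,
                 n_null = x$n_null, null_source = x$null_source)
}

# Shared statistic block for the kin-bias suite: QAP betas (slope on the
# single predictor) for association ~ relatedness within all bats / females /
# males, and association ~ each dyad-type indicator, computed on one
# association matrix. Returns a named numeric vector; NA where unfittable.
kin_bias_betas <- function(assoc, relatedness, sexes) {
  Y <- assoc$sri
  ids <- rownames(Y)
  r <- relatedness[ids, ids]
  sx <- sexes[ids]
  ff <- dyad_type_matrix(sx, "female-female")
  mm <- dyad_type_matrix(sx, "male-male")
  slope <- function(Ysub, Xsub) {
    mask <- lower.tri(Ysub) & is.finite(Ysub) & is.finite(Xsub)
    y <- Ysub[mask]; x <- Xsub[mask]
    if (length(y) < 3 || sd(x) == 0) return(NA_real_)
    unname(stats::cov(x, y) / var(x))
  }
  sub <- function(sex) ids[sx == sex]
  fids <- sub("female"); mids <- sub("male")
  c(
    beta_rel_all = slope(Y, r),
    beta_rel_female = if (length(fids) >= 3) slope(Y[fids, fids], r[fids, fids]) else NA_real_,
    beta_rel_male = if (length(mids) >= 3) slope(Y[mids, mids], r[mids, mids]) else NA_real_,
    beta_type_ff = slope(Y, ff),
    beta_type_mm = slope(Y, mm)
  )
}

#' Kin-biased association suite
#'
#' Aggregates the dyadic tests of kin bias into one tidy report:
#' (i) Mantel tests of each dyad-type indicator against relatedness (node
#' permutation); (ii) QAP of association on each dyad-type indicator against
#' pre-network (datastream) nulls; (iii) QAP of association on relatedness
#' within all bats, within females only, and within males only, against the
#' same nulls. Null networks are generated once from the observed
#' group-by-individual matrix and their statistics are streamed, so memory
#' stays flat regardless of `config$n_networks`.
#'
#' @param gbi Group-by-individual matrix of the association analysis set.
#' @param relatedness Symmetric relatedness matrix covering at least the
#'   `gbi` bats (and the `mantel_bats`).
#' @param config A [perm_config()] for the datastream nulls.
#' @param mantel_bats Bats over which the Mantel tests run (default: all
#'   sexed bats present in `relatedness` — typically the genotyped adults,
#'   a larger set than the well-sampled association subset).
#' @param sexes Named sex vector for `mantel_bats` not in `gbi` (defaults to
#'   the gbi metadata; supply when `mantel_bats` is wider).
#' @param mantel_n_perm Mantel permutations (default 5000).
#' @param period Sampling-period convention for the null networks.
#' @param seed Optional integer seed for the Mantel permutations.
#' @return A tibble of class `kin_bias_report` with columns `test`, `subset`,
#'   `n_bats`, `statistic_name`, `statistic`, `p_value`, `p_display`,
#'   `n_null`.
#' @export
kin_bias_suite <- function(gbi, relatedness, config = perm_config(),
                           mantel_bats = NULL, sexes = NULL,
                           mantel_n_perm = 5000,
                           period = c("date-population", "event"),
                           seed = NULL) {
  period <- match.arg(period)
  gbi_sexes <- setNames(gbi$bats$sex, gbi$bats$bat_id)
  if (is.null(sexes)) sexes <- gbi_sexes
  if (is.null(mantel_bats)) {
    mantel_bats <- intersect(rownames(relatedness), names(sexes))
  }

  # --- Mantel: dyad type vs relatedness over the (wider) genotyped set
  msex <- sexes[mantel_bats]
  rm_sub <- relatedness[mantel_bats, mantel_bats]
  mantel_rows <- purrr::map_dfr(
    c("female-female", "male-male", "female-male"),
    function(tp) {
      B <- dyad_type_matrix(msex, tp)
      mt <- mantel_test(B, rm_sub, n_perm = mantel_n_perm, seed = seed)
      tibble::tibble(test = "mantel_dyadtype_vs_relatedness", subset = tp,
                     n_bats = mt$n_bats, statistic_name = "mantel_r",
                     statistic = mt$r, p_value = mt$p_value,
                     p_display = mt$p_display, n_null = mt$n_perm)
    })

  # --- QAP against datastream nulls, streamed
  assoc <- simple_ratio_index(gbi, period = period)
  obs <- kin_bias_betas(assoc, relatedness, gbi_sexes)
  nulls <- generate_null_networks(gbi, config, period = period,
                                  fun = function(a, g) kin_bias_betas(a, relatedness, gbi_sexes))
  null_mat <- do.call(rbind, nulls)

  qap_row <- function(stat, test, subset, n_bats) {
    nb <- null_mat[, stat]
    nb <- nb[!is.na(nb)]
    if (is.na(obs[[stat]]) || length(nb) == 0) {
      return(tibble::tibble(test = test, subset = subset, n_bats = n_bats,
                            statistic_name = "qap_beta", statistic = obs[[stat]],
                            p_value = NA_real_, p_display = NA_character_,
                            n_null = length(nb)))
    }
    ep <- empirical_p(obs[[stat]], nb)
    tibble::tibble(test = test, subset = subset, n_bats = n_bats,
                   statistic_name = "qap_beta", statistic = obs[[stat]],
                   p_value = ep$p_value, p_display = ep$p_display,
                   n_null = length(nb))
  }
  n_all <- nrow(gbi$bats)
  n_f <- sum(gbi$bats$sex == "female")
  n_m <- sum(gbi$bats$sex == "male")
  qap_rows <- dplyr::bind_rows(
    qap_row("beta_type_ff", "qap_association_on_dyadtype", "female-female", n_all),
    qap_row("beta_type_mm", "qap_association_on_dyadtype", "male-male", n_all),
    qap_row("beta_rel_all", "qap_association_on_relatedness", "all", n_all),
    qap_row("beta_rel_female", "qap_association_on_relatedness", "female", n_f),
    qap_row("beta_rel_male", "qap_association_on_relatedness", "male", n_m)
  )

  out <- dplyr::bind_rows(mantel_rows, qap_rows)
  class(out) <- c("kin_bias_report", class(out))
  out
}
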