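random_sym <- function(n, seed, names = sprintf("b%02d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- NA
  dimnames(m) <- list(names, names)
  m
}

test_that("Mantel r is 1 on identical matrices and flagged on constants", {
  A <- random_sym(8, 1)
  mt <- mantel_test(A, A, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  B <- A
  B[] <- 0.3
  diag(B) <- NA
  expect_warning(mt2 <- mantel_test(A, B, n_perm = 99), "zero variance")
  expect_true(is.na(mt2$r))
  expect_error(mantel_test(A[1:2, 1:2], A[1:2, 1:2]), "at least 3")
})

test_that("Mantel r is invariant to simultaneous reordering of both matrices", {
  A <- random_sym(9, 2)
  B <- random_sym(9, 3)
  r0 <- mantel_test(A, B, n_perm = 9, seed = 1)$r
  set.seed(4)
  ord <- sample(9)
  r1 <- mantel_test(A[ord, ord], B[ord, ord], n_perm = 9, seed = 1)$r
  expect_equal(r1, r0)
})

test_that("Mantel r agrees with vegan on complete matrices", {
  skip_if_not_installed("vegan")
  A <- random_sym(10, 5); diag(A) <- 0
  B <- random_sym(10, 6); diag(B) <- 0
  ours <- mantel_test(A, B, n_perm = 9, seed = 1)$r
  ref <- vegan::mantel(as.dist(A), as.dist(B), permutations = 9)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("Mantel p-values are uniform under independence", {
  set.seed(42)
  ps <- vapply(1:200, function(k) {
    A <- random_sym(8, k * 2)
    B <- random_sym(8, k * 2 + 1)
    mantel_test(A, B, n_perm = 99, alternative = "greater")$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("dyad-type matrices partition all mixed-sex-defined dyads", {
  sexes <- c(A = "female", B = "female", C = "male", D = "male", E = "male")
  ff <- dyad_type_matrix(sexes, "female-female")
  mm <- dyad_type_matrix(sexes, "male-male")
  fm <- dyad_type_matrix(sexes, "female-male")
  expect_equal(sum(ff[lower.tri(ff)]), choose(2, 2))  # choose(n_F, 2) = 1
  expect_equal(sum(mm[lower.tri(mm)]), choose(3, 2))
  total <- ff + mm + fm
  expect_true(all(total[lower.tri(total)] == 1))
  expect_error(dyad_type_matrix(c(A = "f")), "unknown sex")
})

test_that("QAP recovers an identity regression exactly", {
  X <- random_sym(8, 7)
  res <- qap_regression(X, list(same = X), n_perm = 19, seed = 1)
  expect_equal(res$coefficients$beta[res$coefficients$term == "same"], 1,
               tolerance = 1e-12)
  expect_equal(res$coefficients$beta[res$coefficients$term == "(Intercept)"], 0,
               tolerance = 1e-12)
})

test_that("QAP beta on an orthogonal predictor is ~0 with large p", {
  # construct a predictor orthogonal to the response over the dyads
  n <- 8
  ids <- sprintf("b%02d", 1:n)
  nd <- n * (n - 1) / 2
  set.seed(10)
  y <- rnorm(nd)
  x <- rnorm(nd)
  yc <- y - mean(y)
  x <- x - mean(x)
  x <- x - sum(x * yc) / sum(yc^2) * yc  # cov(x, y) = 0 exactly
  mk <- function(v) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[lower.tri(m)] <- v
    m <- m + t(m)
    diag(m) <- NA
    m
  }
  res <- qap_regression(mk(y), list(orth = mk(x)), n_perm = 499, seed = 2)
  beta <- res$coefficients$beta[res$coefficients$term == "orth"]
  # cov(x, y) = 0 by construction, so beta = 0 up to floating point
  expect_equal(beta, 0, tolerance = 1e-10)
  expect_gt(res$coefficients$p_value[res$coefficients$term == "orth"], 0.5)
})

test_that("QAP betas match the normal-equations oracle on random instances", {
  for (seed in 1:6) {
    Y <- random_sym(10, seed * 11)
    P1 <- random_sym(10, seed * 11 + 1)
    P2 <- random_sym(10, seed * 11 + 2)
    res <- qap_regression(Y, list(a = P1, b = P2), n_perm = 5, seed = 1)
    mask <- lower.tri(Y)
    X <- cbind(1, P1[mask], P2[mask])
    expect_equal(res$coefficients$beta, ols_oracle(Y[mask], X), tolerance = 1e-10)
  }
})

test_that("collinear or constant predictors raise informative errors", {
  Y <- random_sym(8, 30)
  P <- random_sym(8, 31)
  expect_error(qap_regression(Y, list(a = P, b = 2 * P), n_perm = 5),
               "collinear.*b")
  C <- P
  C[] <- 1
  diag(C) <- NA
  expect_error(qap_regression(Y, list(flat = C), n_perm = 5), "constant.*flat")
})

test_that("custom-null QAP refits against unpermuted predictors", {
  gbi <- swap_fixture(seed = 14)
  assoc <- simple_ratio_index(gbi)
  rel <- random_sym(ncol(gbi$M), 15, names = colnames(gbi$M))
  nulls <- generate_null_networks(gbi, perm_config(n_networks = 30, seed = 3))
  res <- qap_regression(assoc, list(relatedness = rel), null = "custom",
                        null_networks = nulls)
  expect_equal(res$n_null, 30)
  expect_equal(res$null_source, "custom")
  # each null beta equals an independent OLS fit on that null network
  mask <- lower.tri(assoc$sri) & is.finite(assoc$sri) & is.finite(rel)
  X <- cbind(1, rel[mask])
  b7 <- ols_oracle(nulls[[7]]$sri[mask], X)
  expect_equal(unname(res$null_betas[7, ]), b7, tolerance = 1e-12)
})

test_that("the kin-bias suite reproduces qap_regression slopes and aggregates cleanly", {
  cfg <- sim_config(n_founders = 16, n_years = 3, n_roosts = 4, groups_per_day = 2,
                    captures_per_year = 14, days_per_year = 20, seed = 31)
  sim <- simulate_colony(cfg)
  gbi <- build_gbi(filter_captures(sim$dataset, min_sightings = 3))
  pc <- perm_config(n_networks = 25, swaps_per_sample = 20, burn_in_swaps = 100,
                    seed = 9)
  rep <- kin_bias_suite(gbi, sim$relatedness, config = pc, mantel_n_perm = 49,
                        seed = 2)
  expect_s3_class(rep, "kin_bias_report")
  expect_setequal(unique(rep$test),
                  c("mantel_dyadtype_vs_relatedness", "qap_association_on_dyadtype",
                    "qap_association_on_relatedness"))
  # observed QAP slope for the all-adults relatedness model matches the
  # full OLS route
  assoc <- simple_ratio_index(gbi)
  ids <- rownames(assoc$sri)
  direct <- qap_regression(assoc, list(r = sim$relatedness[ids, ids]),
                           n_perm = 5, seed = 1)
  suite_beta <- rep$statistic[rep$test == "qap_association_on_relatedness" &
                                rep$subset == "all"]
  expect_equal(suite_beta, direct$coefficients$beta[2], tolerance = 1e-12)
})
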