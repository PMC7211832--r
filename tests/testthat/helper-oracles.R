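# Independent oracles and tiny fixture builders used across the suite.

# --- capture-table builders -------------------------------------------------

capture_row <- function(bat, date, roost, pop = "P1", sex = "female",
                        age = "adult", repro = NA_character_) {
  tibble::tibble(bat_id = bat, date = as.Date(date), roost_id = roost,
                 population = pop, sex = sex, age_class = age,
                 repro_status = repro)
}

# Random small dataset: bats with fixed sex/population, events on random
# (date, roost) keys; occasionally the same bat is captured in two roosts on
# one date, exercising the multi-event sampling-period path.
random_small_ds <- function(seed, n_bats = 6, n_events = 10) {
  set.seed(seed)
  bats <- tibble::tibble(
    bat_id = sprintf("b%02d", seq_len(n_bats)),
    sex = sample(c("female", "male"), n_bats, replace = TRUE),
    population = sample(c("P1", "P2"), n_bats, replace = TRUE)
  )
  dates <- as.Date("2015-06-01") + 0:5
  roosts <- tibble::tibble(
    roost_id = sprintf("r%02d", 1:6),
    population = rep(c("P1", "P2"), each = 3)
  )
  keys <- expand.grid(date = dates, roost_id = roosts$roost_id,
                      stringsAsFactors = FALSE)
  keys <- keys[sample(nrow(keys), n_events), ]
  rows <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    pop <- roosts$population[roosts$roost_id == keys$roost_id[i]]
    pool <- bats[bats$population == pop, ]
    if (nrow(pool) == 0) return(NULL)
    members <- pool[sample(nrow(pool), sample(nrow(pool), 1)), ]
    tibble::tibble(bat_id = members$bat_id, date = keys$date[i],
                   roost_id = keys$roost_id[i], population = pop,
                   sex = members$sex, age_class = "adult",
                   repro_status = NA_character_)
  })
  # same-event duplicates impossible by construction (sampling w/o replacement)
  as_capture_dataset(rows)
}

# --- simple-ratio-index oracle ----------------------------------------------

# Brute-force four-category enumeration per dyad over sampling periods.
sri_oracle <- function(gbi, period = "date-population") {
  M <- gbi$M
  pid <- if (period == "event") as.character(seq_len(nrow(M))) else
    paste(gbi$events$date, gbi$events$population, sep = "|")
  bats <- colnames(M)
  n <- length(bats)
  sri <- matrix(NA_real_, n, n, dimnames = list(bats, bats))
  denom <- matrix(0, n, n, dimnames = list(bats, bats))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- y_ab <- y_a <- y_b <- 0
      for (p in unique(pid)) {
        rows <- which(pid == p)
        seen_a <- any(M[rows, i] == 1)
        seen_b <- any(M[rows, j] == 1)
        together <- any(M[rows, i] == 1 & M[rows, j] == 1)
        if (together) x <- x + 1
        else if (seen_a && seen_b) y_ab <- y_ab + 1
        else if (seen_a) y_a <- y_a + 1
        else if (seen_b) y_b <- y_b + 1
      }
      d <- x + y_ab + y_a + y_b
      denom[i, j] <- denom[j, i] <- d
      if (d > 0) sri[i, j] <- sri[j, i] <- x / d
    }
  }
  list(sri = sri, denom = denom)
}

# --- pedigree kinship path-counting oracle ----------------------------------

# Wright's path-counting rule: r(i,j) = 2 f(i,j), with
# f(i,j) = sum over common ancestors A and over pairs of ancestor paths
# (i..A, j..A) sharing only A of (1/2)^(n_i + n_j + 1) * (1 + F_A),
# F_A = f(mother_A, father_A). Independent of the recursive implementation.
kinship_path_oracle <- function(ped) {
  ids <- ped$id
  mo <- setNames(ped$mother_id, ids)
  fa <- setNames(ped$father_id, ids)
  paths_up <- function(x) {
    res <- list(x)
    for (p in c(mo[[x]], fa[[x]])) {
      if (!is.na(p)) {
        for (pp in paths_up(p)) res <- c(res, list(c(x, pp)))
      }
    }
    res
  }
  all_paths <- lapply(ids, paths_up)
  names(all_paths) <- ids
  F_inb <- new.env()
  f_kin <- function(i, j) {
    total <- 0
    for (pi in all_paths[[i]]) {
      for (pj in all_paths[[j]]) {
        A <- pi[length(pi)]
        if (pj[length(pj)] != A) next
        shared <- intersect(pi, pj)
        if (length(shared) != 1 || shared != A) next
        total <- total + 0.5^((length(pi) - 1) + (length(pj) - 1) + 1) *
          (1 + inbreeding(A))
      }
    }
    total
  }
  inbreeding <- function(a) {
    if (!is.null(F_inb[[a]])) return(F_inb[[a]])
    val <- if (is.na(mo[[a]]) || is.na(fa[[a]])) 0 else f_kin(mo[[a]], fa[[a]])
    F_inb[[a]] <- val
    val
  }
  n <- length(ids)
  r <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) r[i, j] <- r[j, i] <- 2 * f_kin(ids[i], ids[j])
    }
  }
  diag(r) <- 1
  r
}

# --- exhaustive two-group permutation oracle --------------------------------

exhaustive_perm_p <- function(values, labels, statistic) {
  f <- factor(labels)
  n1 <- sum(f == levels(f)[1])
  obs <- statistic(values[f == levels(f)[1]], values[f == levels(f)[2]])
  splits <- combn(length(values), n1)
  stats <- apply(splits, 2, function(idx) statistic(values[idx], values[-idx]))
  pg <- sum(stats >= obs) / length(stats)
  pl <- sum(stats <= obs) / length(stats)
  min(1, 2 * min(pg, pl))
}

# --- OLS normal-equations oracle --------------------------------------------

ols_oracle <- function(y, X) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# --- reachable-configuration enumeration for the swap chain -----------------

# Breadth-first enumeration of all membership configurations reachable by
# legal swaps, using an R re-implementation of the swap rule (independent of
# the compiled engine). Configurations are canonical strings of each event's
# sorted member set.
enumerate_reachable <- function(M, stratum) {
  key <- function(m) paste(apply(m, 1, function(r) paste(which(r == 1), collapse = ",")),
                           collapse = ";")
  legal_moves <- function(m) {
    obs <- which(m == 1, arr.ind = TRUE)
    out <- list()
    for (i in seq_len(nrow(obs))) {
      for (j in seq_len(nrow(obs))) {
        if (i >= j) next
        if (stratum[obs[i, 1]] != stratum[obs[j, 1]]) next
        e1 <- obs[i, 1]; b1 <- obs[i, 2]
        e2 <- obs[j, 1]; b2 <- obs[j, 2]
        if (e1 == e2 || b1 == b2) next
        if (m[e1, b2] == 1 || m[e2, b1] == 1) next
        m2 <- m
        m2[e1, b1] <- 0L; m2[e1, b2] <- 1L
        m2[e2, b2] <- 0L; m2[e2, b1] <- 1L
        out <- c(out, list(m2))
      }
    }
    out
  }
  seen <- new.env()
  queue <- list(M)
  seen[[key(M)]] <- TRUE
  while (length(queue) > 0) {
    m <- queue[[1]]
    queue <- queue[-1]
    for (m2 in legal_moves(m)) {
      k <- key(m2)
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        queue <- c(queue, list(m2))
      }
    }
  }
  ls(seen)
}

# --- compact stratified gbi fixture ------------------------------------------

# One population, three roosts, one year: one (population, roost, year)
# stratum per roost with enough observations to permute.
swap_fixture <- function(seed = 1, n_bats = 8, n_events = 12) {
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(n_events), function(e) {
    bats <- sample(sprintf("b%02d", seq_len(n_bats)), sample(2:4, 1))
    tibble::tibble(bat_id = bats,
                   date = as.Date("2015-06-01") + e,
                   roost_id = sample(c("r1", "r2", "r3"), 1),
                   population = "P1",
                   sex = rep(c("female", "male"), length.out = length(bats)),
                   age_class = "adult", repro_status = NA_character_)
  })
  build_gbi(as_capture_dataset(rows))
}
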