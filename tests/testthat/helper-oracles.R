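# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own code paths.

# Run counter via run-length encoding (independent of the transition scan).
oracle_runs <- function(pattern) {
  r <- rle(as.logical(pattern))
  sum(r$values)
}

oracle_wrt <- function(pattern) {
  p <- as.logical(pattern)
  t_runs <- oracle_runs(p)
  if (t_runs == 0) 0 else 100 * (sum(p) / t_runs) / length(p)
}

# Pairwise Bray-Curtis by direct summation.
oracle_bray <- function(a, b) {
  den <- sum(a + b)
  if (den == 0) 0 else sum(abs(a - b)) / den
}

# Gower distance for one species pair under a schema, by its definition.
oracle_gower_pair <- function(xi, xj, schema, ranges, weights) {
  num <- 0
  den <- 0
  for (k in seq_along(schema)) {
    tr <- schema[[k]]
    vi <- xi[[tr$name]]
    vj <- xj[[tr$name]]
    if (is.na(vi) || is.na(vj)) next
    comp <- if (tr$kind == "quantitative") {
      r <- ranges[[tr$name]]
      if (r > 0) abs(as.numeric(vi) - as.numeric(vj)) / r else 0
    } else {
      as.numeric(as.character(vi) != as.character(vj))
    }
    num <- num + weights[k] * comp
    den <- den + weights[k]
  }
  if (den == 0) NA_real_ else num / den
}

oracle_gower <- function(traits, weights = NULL) {
  schema <- attr(traits, "schema")
  if (is.null(weights)) weights <- rep(1, length(schema))
  ranges <- lapply(schema, function(tr) {
    if (tr$kind == "quantitative") {
      diff(range(traits[[tr$name]], na.rm = TRUE))
    } else {
      NA_real_
    }
  })
  n <- nrow(traits)
  d <- matrix(0, n, n, dimnames = list(traits$species, traits$species))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- oracle_gower_pair(traits[i, ], traits[j, ],
                                              schema, ranges, weights)
    }
  }
  d
}

# Exact one-way PERMANOVA p-value by enumerating 2-group assignments with
# vegan::adonis2 as the F oracle (choose(n, n1) assignments).
oracle_permanova_2group_p <- function(d, n1) {
  n <- nrow(d)
  f_of <- function(g) {
    fit <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 0)
    fit$F[1]
  }
  obs <- f_of(factor(rep(c("a", "b"), c(n1, n - n1))))
  combos <- utils::combn(n, n1)
  fs <- apply(combos, 2, function(idx) {
    g <- rep("b", n)
    g[idx] <- "a"
    f_of(factor(g))
  })
  list(F = obs, p = mean(fs >= obs - 1e-12), n_assign = ncol(combos))
}

# Exact two-sided Spearman p by enumeration over all rank permutations.
oracle_spearman_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rho_obs <- stats::cor(x, y, method = "spearman")
  rhos <- vapply(perms(y), function(p) stats::cor(x, p, method = "spearman"),
                 numeric(1))
  min(1, 2 * min(mean(rhos <= rho_obs + 1e-12),
                 mean(rhos >= rho_obs - 1e-12)))
}

# Survey series encoding given presence patterns with exact relative covers:
# each focal species gets its own unit shared with one ubiquitous filler
# species, covers scaled so the focal share equals `relcov` at presence.
patterns_series <- function(patterns, relcov, site = "demo",
                            surveys = seq_len(ncol(patterns))) {
  n_sp <- nrow(patterns)
  species <- c(rownames(patterns) %||% paste0("sp_", seq_len(n_sp)), "filler")
  units <- paste0("u", seq_len(n_sp))
  Z <- ncol(patterns)
  cover <- array(0, dim = c(n_sp, n_sp + 1, Z),
                 dimnames = list(units, species, surveys))
  for (i in seq_len(n_sp)) {
    cover[i, i, ] <- ifelse(patterns[i, ] == 1, 10 * relcov[i], 0)
    cover[i, n_sp + 1, ] <- 10 * (1 - relcov[i])
  }
  survey_series(site, surveys, units, species, cover)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The seven worked occupancy patterns of the persistence index description.
table4_patterns <- function() {
  m <- rbind(
    sp_1 = c(1, 0, 1, 0, 1, 0, 1, 0),
    sp_2 = c(1, 1, 0, 0, 0, 0, 0, 0),
    sp_3 = c(0, 0, 1, 1, 0, 0, 1, 0),
    sp_4 = c(0, 0, 1, 1, 1, 0, 1, 0),
    sp_5 = c(1, 1, 1, 1, 1, 1, 1, 1),
    sp_6 = c(1, 1, 1, 1, 1, 1, 1, 0),
    sp_7 = c(1, 1, 1, 0, 1, 1, 0, 0)
  )
  attr(m, "relcov") <- c(0.5, 0.6, 0.3, 0.4, 0.7, 0.8, 0.5)
  m
}

# Small complete random trait table for property tests.
random_trait_table <- function(n, seed) {
  schema <- default_trait_schema()
  withr::with_seed(seed, trait_table(data.frame(
    species = paste0("s", seq_len(n)),
    seed_mass = stats::rlnorm(n, 0.7, 1),
    bud_bank = stats::runif(n) < 0.5,
    sla = stats::runif(n, 5, 45),
    veg_mobility = sample(c("none", "slow", "fast"), n, replace = TRUE),
    leaf_anatomy = sample(c("helomorphic", "hygromorphic", "mesomorphic",
                            "scleromorphic"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ), schema))
}
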