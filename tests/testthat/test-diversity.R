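test_that("gower distance reproduces worked mixed-type examples", {
  schema <- default_trait_schema()
  two <- trait_table(data.frame(
    species = c("s1", "s2"),
    seed_mass = c(1, 1), bud_bank = c(TRUE, FALSE), sla = c(20, 20),
    veg_mobility = c("slow", "slow"),
    leaf_anatomy = c("mesomorphic", "mesomorphic")
  ), schema)
  # five equal-weight traits, only the binary one differs
  expect_equal(gower_matrix(two)["s1", "s2"], 0.2)
  # identical rows
  same <- two
  same$bud_bank <- c(TRUE, TRUE)
  expect_equal(gower_matrix(trait_table(as.data.frame(same), schema))["s1", "s2"], 0)
  # a single quantitative trait at the pool extremes scores 1
  one_tr <- list(sla = list(name = "sla", kind = "quantitative", unit = ""))
  pool <- trait_table(data.frame(species = c("a", "b"), sla = c(5, 45)),
                      one_tr)
  expect_equal(gower_matrix(pool)["a", "b"], 1)
})

test_that("gower matches the definitional oracle, with and without weights", {
  for (seed in c(3, 14, 25)) {
    tt <- random_trait_table(7, seed)
    expect_equal(gower_matrix(tt), oracle_gower(tt), tolerance = 1e-12)
    w <- c(seed_mass = 2, bud_bank = 1, sla = 0.5, veg_mobility = 1,
           leaf_anatomy = 3)
    expect_equal(gower_matrix(tt, weights = w),
                 oracle_gower(tt, weights = unname(w[names(attr(tt, "schema"))])),
                 tolerance = 1e-12)
  }
})

test_that("gower handles missing traits by pairwise deletion", {
  schema <- default_trait_schema()
  tt <- trait_table(data.frame(
    species = c("s1", "s2", "s3"),
    seed_mass = c(1, 5, NA), bud_bank = c(TRUE, FALSE, TRUE),
    sla = c(10, 30, 20), veg_mobility = c("fast", "fast", NA),
    leaf_anatomy = c("mesomorphic", "mesomorphic", "scleromorphic")
  ), schema)
  expect_equal(gower_matrix(tt), oracle_gower(tt), tolerance = 1e-12)
  # a pair sharing no non-missing trait is an error naming the pair
  all_na <- trait_table(data.frame(
    species = c("x", "y", "z"),
    seed_mass = c(1, NA, 2), bud_bank = c(NA, TRUE, FALSE),
    sla = c(3, NA, 1), veg_mobility = c(NA, "fast", "slow"),
    leaf_anatomy = c(NA, NA, "mesomorphic")
  ), schema)
  expect_error(gower_matrix(all_na), "x / y|y / x")
})

test_that("mean pairwise distance follows its definition", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["a", "c"] <- d["c", "a"] <- 2
  d["b", "c"] <- d["c", "b"] <- 3
  expect_equal(mpd(d, c("a", "b", "c")), 2)
  expect_equal(mpd(d, c("a", "c")), 2)
  expect_true(is.na(mpd(d, "a")))
  expect_error(mpd(d, c("a", "q")), "not in")
  skip_if_not_installed("picante")
  tt <- random_trait_table(10, 8)
  g <- gower_matrix(tt)
  samp <- matrix(c(rep(1, 6), rep(0, 4)), nrow = 1,
                 dimnames = list("u1", tt$species))
  expect_equal(mpd(g, tt$species[1:6]),
               unname(picante::mpd(samp, g)), tolerance = 1e-12)
})

test_that("neighbor joining solves the three-point configuration", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  term <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(term[["A"]], 1)
  expect_equal(term[["B"]], 2)
  expect_equal(term[["C"]], 3)
  p <- patristic_distances(tr)
  expect_equal(p[rownames(d), colnames(d)], d)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("nj recovers additive matrices from random trees", {
  for (seed in 1:10) {
    tr <- withr::with_seed(seed, {
      t0 <- ape::rtree(sample(5:12, 1))
      t0$edge.length <- stats::runif(nrow(t0$edge), 0.1, 2)
      t0
    })
    d <- stats::cophenetic(tr)
    rec <- neighbor_joining(d)
    drec <- patristic_distances(rec)[rownames(d), colnames(d)]
    expect_lt(max(abs(drec - d)), 1e-9)
  }
})

test_that("identical taxa are joined with zero-length branches", {
  d <- matrix(c(0, 0, 4, 4,
                0, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), nrow = 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  p <- patristic_distances(tr)
  expect_equal(p["a", "b"], 0)
  expect_true(all(tr$edge.length >= 0))
})

test_that("patristic distances cover star, zero and nodal fallback cases", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  p <- patristic_distances(star)
  expect_true(all(p[upper.tri(p)] == 4))
  zero <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  expect_true(all(patristic_distances(zero) == 0))
  topo <- ape::read.tree(text = "((A,B),(C,D));")
  expect_message(p2 <- patristic_distances(topo), "nodal")
  expect_equal(p2["A", "B"], 2)
})

test_that("diversity scores are invariant to species and unit ordering", {
  st <- simulate_study(sim_config(n_sites = 1, n_units = 12, n_species = 10,
                                  seed = 21))
  s <- st$series[[1]]
  g <- gower_matrix(st$traits)
  pdm <- patristic_distances(st$tree)
  sc <- diversity_scores(s, g, pdm)
  perm <- sample(length(s$species))
  s2 <- survey_series(s$site, s$surveys, rev(s$units), s$species[perm],
                      s$cover[rev(seq_along(s$units)), perm, , drop = FALSE],
                      s$occupancy[rev(seq_along(s$units)), perm, ,
                                  drop = FALSE])
  sc2 <- diversity_scores(s2, g, pdm)
  m1 <- sc[order(sc$unit), ]
  m2 <- sc2[order(sc2$unit), ]
  expect_equal(m1$fd, m2$fd)
  expect_equal(m1$pd, m2$pd)
})

test_that("fd-pd correlation handles monotone, reversed and toy-exact cases", {
  fd <- (1:10) / 10
  expect_equal(fd_pd_correlation(fd, fd^2)$rho, 1)
  expect_equal(fd_pd_correlation(fd, rev(fd))$rho, -1)
  x <- c(0.12, 0.5, 0.31, 0.9, 0.77, 0.05)
  y <- c(0.3, 0.8, 0.2, 0.65, 0.9, 0.1)
  res <- fd_pd_correlation(x, y)
  expect_equal(res$p_value, oracle_spearman_p(x, y), tolerance = 1e-10)
  expect_error(fd_pd_correlation(c(1, 2), c(1, 2)), "fewer than 3")
  expect_warning(res2 <- fd_pd_correlation(c(fd, NA), c(fd^2, 1)), "dropped")
  expect_equal(res2$n, 10)
})
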