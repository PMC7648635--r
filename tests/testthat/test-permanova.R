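test_that("bray_curtis matches hand values and the vegan reference", {
  x <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["b", "c"], 0.5)
  y <- rbind(c(1, 0), c(0, 3))
  expect_equal(bray_curtis(y)[1, 2], 1) # disjoint support
  expect_error(bray_curtis(rbind(c(-1, 0), c(1, 1))), "negative")

  skip_if_not_installed("vegan")
  for (seed in 1:100) {
    m <- withr::with_seed(seed, matrix(stats::rpois(6 * 10, 3), nrow = 6))
    expect_lt(max(abs(bray_curtis(m) -
                        as.matrix(vegan::vegdist(m, "bray")))), 1e-12)
  }
})

test_that("all-zero row pairs get distance 0 with a warning", {
  m <- rbind(c(0, 0), c(0, 0), c(1, 2))
  expect_warning(d <- bray_curtis(m), "all-zero")
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 1)
})

test_that("trait abundance matrix sums cover by attribute and takes CWMs", {
  schema <- default_trait_schema()
  tt <- trait_table(data.frame(
    species = c("helo_sp", "sclero_sp"),
    seed_mass = c(1, 2), bud_bank = c(TRUE, FALSE), sla = c(20, 10),
    veg_mobility = c("fast", "slow"),
    leaf_anatomy = c("helomorphic", "scleromorphic")
  ), schema)
  cov <- array(0, dim = c(2, 2, 2),
               dimnames = list(c("u1", "u2"), c("helo_sp", "sclero_sp"),
                               c("1999", "2000")))
  cov["u1", "helo_sp", "1999"] <- 30
  cov["u1", "sclero_sp", "1999"] <- 10
  s <- survey_series("A", c(1999, 2000), c("u1", "u2"),
                     c("helo_sp", "sclero_sp"), cov)
  m <- trait_abundance_matrix(s, tt)
  expect_equal(m["u1", "helomorphic"], 30)
  expect_equal(m["u1", "scleromorphic"], 10)
  expect_equal(m["u1", "sla"], (30 * 20 + 10 * 10) / 40) # 17.5
  expect_equal(m["u1", "bud_bank"], 30)
  expect_true(all(m["u2", ] == 0)) # empty unit row
  expect_error(trait_abundance_matrix(s, tt, survey = "1998"), "unknown")
})

test_that("permanova SS partition is additive and scale-invariant", {
  d <- withr::with_seed(5, {
    m <- matrix(stats::runif(8 * 4), nrow = 8)
    as.matrix(stats::dist(m))
  })
  g <- rep(c("a", "b"), each = 4)
  fit <- permanova(d, g, method = "exhaustive")
  expect_equal(fit$ss_between + fit$ss_within, fit$ss_total,
               tolerance = 1e-10)
  expect_gte(fit$r_squared, 0)
  expect_lte(fit$r_squared, 1)
  expect_equal(fit$df_between, 1L)
  expect_equal(fit$df_within, 6L)
  fit2 <- permanova(2 * d, g, method = "exhaustive")
  expect_equal(fit2$pseudo_F, fit$pseudo_F)
  expect_equal(fit2$r_squared, fit$r_squared)
  expect_equal(fit2$p_value, fit$p_value)
})

test_that("permanova statistics agree with vegan::adonis2", {
  skip_if_not_installed("vegan")
  for (seed in 1:5) {
    d <- withr::with_seed(seed, {
      m <- matrix(stats::rlnorm(12 * 6), nrow = 12)
      as.matrix(vegan::vegdist(m, "bray"))
    })
    g <- factor(rep(c("a", "b", "c"), each = 4))
    mine <- permanova(d, g, n_perm = 99, seed = 1, method = "monte_carlo")
    ref <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 0)
    expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
    expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
  }
})

test_that("exhaustive p equals brute-force enumeration on 6 objects", {
  skip_if_not_installed("vegan")
  d <- withr::with_seed(11, {
    m <- matrix(stats::runif(6 * 5), nrow = 6)
    as.matrix(stats::dist(m))
  })
  g <- rep(c("a", "b"), each = 3)
  fit <- permanova(d, g, method = "exhaustive")
  oracle <- oracle_permanova_2group_p(d, 3)
  expect_equal(oracle$n_assign, 20)
  # enumerator counts unordered group-a subsets; assignments double-count
  # the label swap, which leaves F unchanged, so the fractions agree
  expect_equal(fit$p_value, oracle$p)
  expect_equal(fit$n_perm, 20L)
})

test_that("monte-carlo p converges to the exact permutation p", {
  d <- withr::with_seed(2, as.matrix(stats::dist(matrix(stats::runif(16),
                                                        nrow = 8))))
  g <- rep(c("a", "b"), each = 4)
  exact <- permanova(d, g, method = "exhaustive")
  mc <- permanova(d, g, n_perm = 4999, seed = 7, method = "monte_carlo")
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 4999)
  expect_lt(abs(mc$p_value - exact$p_value), 2 * se + 1 / 5000)
})

test_that("permanova is exchangeable under an all-equal distance null", {
  d <- matrix(1, 6, 6)
  diag(d) <- 0
  fit <- permanova(d, rep(c("a", "b"), each = 3), method = "exhaustive")
  expect_equal(fit$p_value, 1) # permuted F distribution identical
  expect_error(permanova(d, rep("a", 6)), "2 groups")
  expect_error(permanova(d, factor(rep(c("a", "b"), each = 3),
                                   levels = c("a", "b", "c"))), "empty group")
})

test_that("the add-one rule keeps monte-carlo p strictly positive", {
  m <- rbind(matrix(0, 4, 3), matrix(10, 4, 3)) + diag(0.1, 8, 3)[, 1:3]
  d <- as.matrix(stats::dist(m))
  fit <- permanova(d, rep(c("a", "b"), each = 4), n_perm = 99, seed = 3,
                   method = "monte_carlo")
  expect_gte(fit$p_value, 1 / 100)
})
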