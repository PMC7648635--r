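test_that("association test attains the permutation p floor on strong signal", {
  x <- 1:20
  y <- 2 * x + 0.1
  res <- association_test(x, y, n_perm = 999, seed = 4)
  expect_equal(res$p_value, 1 / 1000)
  expect_equal(res$kind, "ordered")
})

test_that("association test conventions: constant x, missing x, few cases", {
  y <- stats::rnorm(10)
  res <- association_test(rep(1, 10), y, n_perm = 99, seed = 1)
  expect_equal(res$p_value, 1)
  x <- c(NA, NA, 1:8)
  res2 <- association_test(x, y, n_perm = 99, seed = 1)
  expect_equal(res2$n, 8)
  expect_error(association_test(c(NA, 1, NA), c(1, 2, 3), n_perm = 99),
               "fewer than 2")
})

test_that("association test is deterministic given its seed", {
  x <- withr::with_seed(1, stats::rnorm(30))
  y <- withr::with_seed(2, stats::rnorm(30))
  a <- association_test(x, y, n_perm = 199, seed = 11)
  b <- association_test(x, y, n_perm = 199, seed = 11)
  expect_identical(a, b)
  g <- rep(c("u", "v", "w"), 10)
  a2 <- association_test(g, y, n_perm = 199, seed = 11)
  expect_equal(a2$kind, "categorical")
  expect_identical(a2, association_test(g, y, n_perm = 199, seed = 11))
})

test_that("split variable selection finds planted signal and breaks ties", {
  set.seed(77)
  n <- 120
  traits <- data.frame(
    signal = stats::rnorm(n),
    noise1 = stats::rnorm(n), noise2 = stats::rnorm(n),
    noise3 = sample(c("a", "b", "c"), n, TRUE),
    noise4 = stats::runif(n) < 0.5
  )
  y <- 10 * traits$signal + stats::rnorm(n)
  sel <- select_split_variable(traits, y, cit_control(n_perm = 199, seed = 5))
  expect_equal(sel$trait, "signal")
  expect_lt(sel$p_adj, 0.05)
  # all-constant candidates: nothing selectable
  const <- data.frame(a = rep(1, n), b = rep("x", n))
  expect_null(select_split_variable(const, y, cit_control(n_perm = 199)))
  # duplicated informative trait: declared order breaks the tie
  dup <- data.frame(first = traits$signal, second = traits$signal)
  sel2 <- select_split_variable(dup, y, cit_control(n_perm = 199, seed = 5))
  expect_equal(sel2$trait, "first")
})

test_that("best split finds step-function cutpoints and level subsets", {
  x <- c(1, 2, 3, 4, 6, 7, 8, 9)
  y <- c(0, 0, 0, 0, 10, 10, 10, 10)
  sp <- best_split(x, y, min_leaf = 2)
  expect_equal(sp$threshold, 4) # largest observed value of the left group
  xc <- rep(c("A", "B", "C"), each = 6)
  yc <- c(rep(0, 12), rep(10, 6))
  spc <- best_split(xc, yc, min_leaf = 2)
  expect_setequal(spc$levels_left, c("A", "B"))
  expect_setequal(spc$levels_right, "C")
  # exactly one admissible split
  sp2 <- best_split(c(1, 1, 2, 2), c(5, 6, 1, 2), min_leaf = 2)
  expect_equal(sp2$threshold, 1)
  # min_leaf can rule out every partition
  expect_null(best_split(c(1, 1, 1, 2), c(5, 6, 1, 2), min_leaf = 2))
})

test_that("grown trees recover planted structure and stay consistent", {
  set.seed(31)
  n <- 400
  traits <- data.frame(
    seed_mass = stats::rlnorm(n, 0.7, 1.2),
    bud_bank = stats::runif(n) < 0.6,
    sla = stats::rnorm(n, 25, 8),
    veg_mobility = sample(c("none", "slow", "fast"), n, TRUE),
    leaf_anatomy = sample(c("helomorphic", "hygromorphic", "mesomorphic",
                            "scleromorphic"), n, TRUE)
  )
  y <- 30 + 40 * traits$bud_bank + stats::rnorm(n, sd = 15)
  ctrl <- cit_control(n_perm = 199, seed = 3, max_depth = 1)
  fit <- grow_tree(y, traits, ctrl)
  expect_equal(fit$root$split$trait, "bud_bank")
  expect_equal(fit$root$left$n + fit$root$right$n, fit$root$n)
  expect_lt(fit$root$split$p_adj, 0.05)
  # duplicating every observation preserves the topology
  fit2 <- grow_tree(rep(y, 2), rbind(traits, traits), ctrl)
  expect_equal(fit2$root$split$trait, "bud_bank")
  # with alpha -> 1 and depth 1 the root equals the argmin-p trait
  ctrl_all <- cit_control(alpha = 0.999, n_perm = 199, seed = 3,
                          max_depth = 1)
  ctrl_root <- ctrl_all
  ctrl_root$seed <- ctrl_root$seed + 101L # the root node's derived seed
  sel <- select_split_variable(traits, y, ctrl_root)
  fit3 <- grow_tree(y, traits, ctrl_all)
  expect_equal(fit3$root$split$trait, sel$trait)
  expect_error(grow_tree(numeric(0), traits), "empty")
})

test_that("every reported split is significant and leaf sizes respect bounds", {
  set.seed(12)
  n <- 300
  traits <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n),
                       c = sample(c("x", "y"), n, TRUE))
  y <- 10 * (traits$a > 0) + 5 * (traits$c == "x") + stats::rnorm(n)
  ctrl <- cit_control(n_perm = 499, seed = 8)
  fit <- grow_tree(y, traits, ctrl)
  check <- function(node) {
    if (is.null(node$split)) {
      expect_gte(node$n, ctrl$min_leaf)
      return(invisible())
    }
    expect_lt(node$split$p_adj, ctrl$alpha)
    expect_equal(node$left$n + node$right$n, node$n)
    check(node$left)
    check(node$right)
  }
  check(fit$root)
  expect_gt(summary(fit)$depth, 1)
})

test_that("tree rendering shows splits, leaves and thresholds", {
  set.seed(2)
  n <- 200
  traits <- data.frame(sm = stats::rlnorm(n, 1, 1))
  y <- ifelse(traits$sm > 6.9, 80, 20) + stats::rnorm(n)
  fit <- grow_tree(y, traits, cit_control(n_perm = 199, seed = 1,
                                          max_depth = 1))
  txt <- render_tree(fit)
  expect_length(txt, 3) # root split + two leaves
  expect_match(txt[1], "sm <= ")
  thr <- format(round(fit$root$split$threshold, 1))
  expect_true(any(grepl(thr, txt, fixed = TRUE)))
  leaf_only <- grow_tree(stats::rnorm(10), data.frame(x = rep(1, 10)),
                         cit_control(n_perm = 99, min_node = 20))
  expect_length(render_tree(leaf_only), 1)
  js <- cit_to_json(fit)
  expect_match(as.character(js), "\"trait\"")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$root$n, n)
})

test_that("predictions route observations to their leaf means", {
  set.seed(4)
  n <- 200
  traits <- data.frame(b = stats::runif(n) < 0.5)
  y <- 50 * traits$b + stats::rnorm(n)
  fit <- grow_tree(y, traits, cit_control(n_perm = 199, seed = 2,
                                          max_depth = 1))
  pr <- predict(fit, data.frame(b = c(TRUE, FALSE)))
  expect_equal(pr[1], mean(y[traits$b]), tolerance = 1e-10)
  expect_equal(pr[2], mean(y[!traits$b]), tolerance = 1e-10)
})
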