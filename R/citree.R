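#' Control parameters for conditional inference trees
#'
#' @param alpha Significance level for split acceptance (each split's
#'   Bonferroni-adjusted p must fall below it).
#' @param n_perm Monte-Carlo permutations per association test (>= 99).
#' @param min_node Minimum observations in a node to attempt a split.
#' @param min_leaf Minimum observations in each child.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param seed RNG seed; per-node test seeds are derived deterministically
#'   from it, so the fitted tree is reproducible.
#' @return A list of class `cit_control`.
#' @export
cit_control <- function(alpha = 0.05, n_perm = 9999, min_node = 20,
                        min_leaf = 7, max_depth = 4, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 99, min_leaf >= 1,
            min_node >= 2 * min_leaf || min_node >= 2, max_depth >= 1)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_node = as.integer(min_node),
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "cit_control")
}

#' Permutation test of association between one predictor and a response
#'
#' Rank-based test of independence. For an ordered predictor (numeric,
#' logical or ordered factor) the statistic is the absolute Spearman-type
#' rank correlation between predictor and response ranks; for a categorical
#' predictor it is a Kruskal-Wallis-type between-group statistic on response
#' ranks. Significance is assessed by seeded Monte-Carlo permutation of the
#' response with the add-one rule `p = (b + 1) / (n_perm + 1)`, so the
#' smallest attainable p-value is `1 / (n_perm + 1)`. Cases with a missing
#' predictor value are deleted for this test; a constant predictor returns
#' `p = 1` by convention (no association is testable).
#'
#' @param x Predictor values.
#' @param y Numeric response (non-constant).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List with `statistic`, `p_value`, `n` (complete cases used) and
#'   `kind` (`"ordered"` or `"categorical"`).
#' @export
association_test <- function(x, y, n_perm = 9999, seed = 1) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(y)
  if (n < 2L) stop("fewer than 2 complete cases", call. = FALSE)
  kind <- predictor_kind(x)
  if (length(unique(x)) < 2L) {
    return(list(statistic = 0, z = 0, p_value = 1, n = n, kind = kind))
  }
  ry <- rank(y)
  if (kind == "ordered") {
    rx <- rank(as.numeric(x))
    rxc <- rx - mean(rx)
    if (sum(rxc^2) == 0 || stats::var(ry) == 0) {
      return(list(statistic = 0, z = 0, p_value = 1, n = n, kind = kind))
    }
    stat_fun <- function(r) abs(sum(rxc * r))
  } else {
    g <- factor(x)
    ng <- tabulate(g)
    idx <- as.integer(g)
    stat_fun <- function(r) {
      sums <- rowsum(r, idx, reorder = TRUE)
      sum(sums^2 / ng)
    }
  }
  obs <- stat_fun(ry)
  perm <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) stat_fun(sample(ry)),
                                 numeric(1)))
  b <- sum(perm >= obs - 1e-9)
  sd_perm <- stats::sd(perm)
  z <- if (is.finite(sd_perm) && sd_perm > 0) (obs - mean(perm)) / sd_perm
       else 0
  list(statistic = unname(obs), z = unname(z),
       p_value = (b + 1) / (n_perm + 1), n = n, kind = kind)
}

predictor_kind <- function(x) {
  if (is.numeric(x) || is.logical(x) || is.ordered(x)) "ordered"
  else "categorical"
}

#' Select the split variable by Bonferroni-adjusted permutation tests
#'
#' Tests every candidate predictor against the response with
#' [association_test()], Bonferroni-adjusts the p-values over the number of
#' testable predictors, and returns the predictor with the smallest adjusted
#' p-value provided it falls below `alpha`. Ties are broken by smaller
#' unadjusted p, then — because Monte-Carlo p-values saturate at the floor
#' `1/(n_perm + 1)` whenever no permutation exceeds the observed statistic —
#' by the larger permutation-standardised statistic
#' `(obs - mean(perm)) / sd(perm)`, and finally by declared predictor order.
#'
#' @param traits Data frame of candidate predictors.
#' @param y Numeric response.
#' @param params A [cit_control()].
#' @return `NULL` when no predictor reaches significance, otherwise a list
#'   with `trait`, `p_adj`, `p_raw` and the per-predictor test table `tests`.
#' @export
select_split_variable <- function(traits, y, params = cit_control()) {
  stopifnot(is.data.frame(traits), ncol(traits) >= 1L)
  nm <- names(traits)
  res <- lapply(seq_along(nm), function(j) {
    x <- traits[[j]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L || length(unique(x[ok])) < 2L ||
        length(unique(y[ok])) < 2L) {
      return(NULL)
    }
    at <- association_test(x, y, n_perm = params$n_perm,
                           seed = params$seed + j)
    data.frame(trait = nm[j], statistic = at$statistic, z = at$z,
               p_raw = at$p_value, n = at$n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) return(NULL)
  m <- nrow(res)
  res$p_adj <- pmin(1, res$p_raw * m)
  ord <- order(res$p_adj, res$p_raw, -res$z, match(res$trait, nm))
  best <- res[ord[1], ]
  if (best$p_adj >= params$alpha) return(NULL)
  list(trait = best$trait, p_adj = best$p_adj, p_raw = best$p_raw,
       tests = res)
}

# Standardised two-sample rank statistic |W - E(W)| / sd(W) for a candidate
# left/right partition (sampling without replacement from the rank vector).
two_sample_rank_stat <- function(ry, left) {
  n <- length(ry)
  nl <- sum(left)
  nr <- n - nl
  if (nl == 0L || nr == 0L) return(-Inf)
  s2 <- sum((ry - mean(ry))^2) / n
  v <- nl * nr / (n - 1) * s2
  if (v <= 0) return(-Inf)
  abs(sum(ry[left]) - nl * mean(ry)) / sqrt(v)
}

#' Best binary split of a node on one predictor
#'
#' For an ordered predictor, scans every observed cutpoint `c` and selects
#' the one maximising the standardised two-sample rank statistic between
#' `{x <= c}` and `{x > c}`, subject to both children holding at least
#' `min_leaf` observations; the reported threshold is the largest observed
#' value of the left group. For a categorical predictor, exhausts the binary
#' level-subset partitions (feasible for <= 10 observed levels). Cases with
#' missing `x` are excluded here and routed to the majority child when the
#' tree is grown.
#'
#' @param x Predictor values at the node.
#' @param y Numeric response at the node.
#' @param min_leaf Minimum child size.
#' @return `NULL` when no admissible split exists; otherwise a list with
#'   `kind`, `statistic`, and either `threshold` (ordered) or `levels_left`
#'   and `levels_right` (categorical).
#' @export
best_split <- function(x, y, min_leaf = 7) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  kind <- predictor_kind(x)
  n <- length(y)
  if (n < 2L * min_leaf) return(NULL)
  ry <- rank(y)
  if (kind == "ordered") {
    xn <- as.numeric(x)
    cuts <- sort(unique(xn))
    cuts <- cuts[-length(cuts)]
    best <- NULL
    for (cc in cuts) {
      left <- xn <= cc
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      s <- two_sample_rank_stat(ry, left)
      if (is.null(best) || s > best$statistic + 1e-12) {
        best <- list(kind = "ordered", statistic = s, threshold = cc)
      }
    }
    return(best)
  }
  levs <- if (is.factor(x)) levels(droplevels(x)) else sort(unique(as.character(x)))
  L <- length(levs)
  if (L < 2L) return(NULL)
  if (L > 10L) stop("categorical predictor with > 10 observed levels",
                    call. = FALSE)
  xc <- as.character(x)
  best <- NULL
  # enumerate subsets containing the first level (complement symmetry)
  for (mask in seq.int(0L, 2L^(L - 1L) - 1L)) {
    bits <- c(TRUE, as.logical(bitwAnd(mask, 2L^(seq_len(L - 1L) - 1L))))
    if (all(bits)) next
    left <- xc %in% levs[bits]
    if (sum(left) < min_leaf || sum(!left) < min_leaf) next
    s <- two_sample_rank_stat(ry, left)
    if (is.null(best) || s > best$statistic + 1e-12) {
      best <- list(kind = "categorical", statistic = s,
                   levels_left = levs[bits], levels_right = levs[!bits])
    }
  }
  best
}

#' Grow a conditional inference tree
#'
#' Recursive binary partitioning in which every split must first pass a
#' permutation test of independence: at each node the predictor with the
#' strongest association to the response is selected via Bonferroni-adjusted
#' Monte-Carlo permutation tests ([select_split_variable()]), and growth
#' stops when no test rejects at `alpha`, when a node falls below
#' `min_node`, or at `max_depth`. The fitted object is deterministic given
#' `params$seed`.
#'
#' @param y Numeric response (one value per observation, e.g. the WRT of a
#'   species in a quadrat).
#' @param traits Data frame of predictors aligned with `y`.
#' @param params A [cit_control()].
#' @return An object of class `cit`.
#' @export
grow_tree <- function(y, traits, params = cit_control()) {
  y <- as.numeric(y)
  if (!length(y)) stop("empty observation set", call. = FALSE)
  stopifnot(is.data.frame(traits), nrow(traits) == length(y))
  counter <- new.env(parent = emptyenv())
  counter$next_id <- 1L
  build <- function(idx, depth) {
    id <- counter$next_id
    counter$next_id <- id + 1L
    ys <- y[idx]
    node <- list(
      id = id, n = length(idx),
      summary = c(n = length(idx), mean = mean(ys),
                  q1 = unname(stats::quantile(ys, 0.25)),
                  median = stats::median(ys),
                  q3 = unname(stats::quantile(ys, 0.75)))
    )
    if (depth >= params$max_depth || length(idx) < params$min_node ||
        length(unique(ys)) < 2L) {
      return(node)
    }
    node_params <- params
    node_params$seed <- params$seed + 101L * id
    sel <- select_split_variable(traits[idx, , drop = FALSE], ys, node_params)
    if (is.null(sel)) return(node)
    xs <- traits[idx, sel$trait]
    sp <- best_split(xs, ys, min_leaf = params$min_leaf)
    if (is.null(sp)) return(node)
    goleft <- if (sp$kind == "ordered") {
      as.numeric(xs) <= sp$threshold
    } else {
      ifelse(is.na(xs), NA, as.character(xs) %in% sp$levels_left)
    }
    if (anyNA(goleft)) {
      # missing split-variable values follow the majority child
      goleft[is.na(goleft)] <- mean(goleft, na.rm = TRUE) >= 0.5
    }
    node$split <- c(list(trait = sel$trait, p_adj = sel$p_adj,
                         p_raw = sel$p_raw), sp)
    node$left <- build(idx[goleft], depth + 1L)
    node$right <- build(idx[!goleft], depth + 1L)
    node
  }
  root <- build(seq_along(y), 0L)
  structure(list(root = root, control = params, n = length(y),
                 trait_names = names(traits)),
            class = "cit")
}

#' Fit a conditional inference tree with a formula interface
#'
#' Convenience wrapper around [grow_tree()]: `response ~ trait1 + trait2`
#' (or `response ~ .`) on a data frame, e.g.
#' `conditional_tree(wrt_pa ~ ., persistence_with_traits)`.
#'
#' @param formula Model formula; the response must be numeric.
#' @param data Data frame holding response and predictors.
#' @param control A [cit_control()].
#' @return An object of class `cit`.
#' @export
conditional_tree <- function(formula, data, control = cit_control()) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  traits <- mf[, -1, drop = FALSE]
  fit <- grow_tree(y, traits, params = control)
  fit$formula <- formula
  fit
}

cit_is_leaf <- function(node) is.null(node$split)

# Route observations in `newdata` to leaves; returns leaf summaries.
cit_route <- function(node, row) {
  while (!cit_is_leaf(node)) {
    x <- row[[node$split$trait]]
    goleft <- if (node$split$kind == "ordered") {
      !is.na(x) && as.numeric(x) <= node$split$threshold
    } else {
      !is.na(x) && as.character(x) %in% node$split$levels_left
    }
    if (is.na(x)) goleft <- node$left$n >= node$right$n
    node <- if (goleft) node$left else node$right
  }
  node
}

#' @export
predict.cit <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  vapply(seq_len(nrow(newdata)), function(i) {
    cit_route(object$root, newdata[i, , drop = FALSE])$summary[["mean"]]
  }, numeric(1))
}

format_rule <- function(split) {
  if (split$kind == "ordered") {
    sprintf("%s <= %s", split$trait, format(round(split$threshold, 1)))
  } else {
    sprintf("%s in {%s}", split$trait,
            paste(split$levels_left, collapse = ", "))
  }
}

#' Render a conditional inference tree as indented text
#'
#' One line per node: internal nodes show the split rule and its adjusted
#' p-value; leaves show the observation count and the boxplot summary
#' (median and quartiles) of the response.
#'
#' @param tree A `cit` object.
#' @return Character vector of lines.
#' @export
render_tree <- function(tree) {
  stopifnot(inherits(tree, "cit"))
  lines <- character(0)
  walk <- function(node, indent, branch) {
    pad <- strrep("  ", indent)
    if (cit_is_leaf(node)) {
      s <- node$summary
      lines <<- c(lines, sprintf(
        "%s%s[%d] leaf: n = %d, median = %.1f (q1 %.1f, q3 %.1f)",
        pad, branch, node$id, node$n, s[["median"]], s[["q1"]], s[["q3"]]))
    } else {
      lines <<- c(lines, sprintf(
        "%s%s[%d] %s, p = %s (n = %d)",
        pad, branch, node$id, format_rule(node$split),
        format.pval(node$split$p_adj, digits = 3), node$n))
      walk(node$left, indent + 1, "yes: ")
      walk(node$right, indent + 1, "no:  ")
    }
  }
  walk(tree$root, 0, "")
  lines
}

#' @export
print.cit <- function(x, ...) {
  cat("Conditional inference tree (rank-based permutation splits)\n")
  cat(sprintf("  n = %d, alpha = %g, n_perm = %d, seed = %d\n",
              x$n, x$control$alpha, x$control$n_perm, x$control$seed))
  cat(render_tree(x), sep = "\n")
  invisible(x)
}

#' @export
summary.cit <- function(object, ...) {
  depth <- function(node) {
    if (cit_is_leaf(node)) 0L else 1L + max(depth(node$left), depth(node$right))
  }
  leaves <- function(node) {
    if (cit_is_leaf(node)) 1L else leaves(node$left) + leaves(node$right)
  }
  structure(list(n = object$n, depth = depth(object$root),
                 n_leaves = leaves(object$root),
                 root_trait = if (cit_is_leaf(object$root)) NA_character_
                              else object$root$split$trait),
            class = "summary.cit")
}

#' @export
print.summary.cit <- function(x, ...) {
  cat(sprintf("cit: n = %d, depth = %d, leaves = %d, root split = %s\n",
              x$n, x$depth, x$n_leaves,
              if (is.na(x$root_trait)) "<none>" else x$root_trait))
  invisible(x)
}

#' Serialise a conditional inference tree to JSON
#'
#' @param tree A `cit` object.
#' @param path Optional output path; when supplied the JSON is written there.
#' @return JSON string (invisibly when `path` is given).
#' @export
cit_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "cit"))
  strip <- function(node) {
    out <- list(id = node$id, n = node$n, summary = as.list(node$summary))
    if (!cit_is_leaf(node)) {
      out$split <- node$split
      out$left <- strip(node$left)
      out$right <- strip(node$right)
    }
    out
  }
  js <- jsonlite::toJSON(list(n = tree$n, control = unclass(tree$control),
                              root = strip(tree$root)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
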