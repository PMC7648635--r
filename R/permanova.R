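#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x_ik - x_jk| / sum (x_ik + x_jk)` between the abundance
#' vectors of objects `i` and `j`. A pair of all-zero rows, for which the
#' index is undefined, is assigned distance 0 with a warning so that empty
#' quadrats remain comparable.
#'
#' @param x Nonnegative `objects x variables` matrix or data frame (rows are
#'   e.g. sampling units, columns species or trait attributes).
#' @return Symmetric matrix with zero diagonal and the row names of `x` as
#'   labels.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 objects", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite abundance", call. = FALSE)
  if (any(x < 0)) stop("negative abundance entry", call. = FALSE)
  num <- as.matrix(stats::dist(x, method = "manhattan"))
  rs <- rowSums(x)
  den <- outer(rs, rs, "+")
  d <- num / den
  empty_pair <- den == 0
  if (any(empty_pair[lower.tri(empty_pair)])) {
    warning("all-zero row pair(s): Bray-Curtis undefined, distance set to 0",
            call. = FALSE)
  }
  d[empty_pair] <- 0
  diag(d) <- 0
  if (!is.null(rownames(x))) dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Trait-abundance composition of sampling units
#'
#' Converts a unit-by-species cover slice into a unit-by-trait-attribute
#' matrix: for every binary or categorical attribute the summed cover of the
#' species bearing it, and for every quantitative trait its cover-weighted
#' mean (CWM; 0 for an empty unit). Species missing from the trait table are
#' dropped with a warning; species with a missing value for a given trait are
#' excluded from that trait's columns only.
#'
#' @param series A [survey_series()].
#' @param traits A [trait_table()] covering the series' species.
#' @param survey Survey label; default the first survey.
#' @return Numeric `units x attributes` matrix.
#' @export
trait_abundance_matrix <- function(series, traits, survey = NULL) {
  stopifnot(inherits(series, "survey_series"), inherits(traits, "trait_table"))
  survey <- survey %||% series$surveys[1]
  k <- match(as.character(survey), series$surveys)
  if (is.na(k)) stop("unknown survey label '", survey, "'", call. = FALSE)
  keep <- series$species %in% traits$species
  if (!all(keep)) {
    warning(sum(!keep), " species absent from the trait table dropped",
            call. = FALSE)
  }
  sp <- series$species[keep]
  cov <- matrix(series$cover[, keep, k], nrow = length(series$units),
                dimnames = list(series$units, sp))
  tr <- traits[match(sp, traits$species), , drop = FALSE]
  schema <- trait_schema(traits)
  cols <- list()
  for (ds in schema) {
    v <- tr[[ds$name]]
    if (ds$kind == "quantitative") {
      ok <- !is.na(v)
      num <- cov[, ok, drop = FALSE] %*% v[ok]
      den <- rowSums(cov[, ok, drop = FALSE])
      cols[[ds$name]] <- as.numeric(ifelse(den > 0, num / den, 0))
    } else if (ds$kind == "binary") {
      cols[[ds$name]] <- rowSums(cov[, !is.na(v) & v, drop = FALSE])
    } else {
      for (lev in ds$levels) {
        cols[[lev]] <- rowSums(cov[, !is.na(v) & v == lev, drop = FALSE])
      }
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- series$units
  out
}

#' Standardise columns to unit range
#'
#' Range standardisation `(x - min) / (max - min)` per column, the
#' pre-treatment applied to trait-abundance matrices before Bray-Curtis;
#' constant columns map to 0.
#'
#' @param x Numeric matrix.
#' @return Matrix with all columns in `[0, 1]`.
#' @export
range_standardise <- function(x) {
  x <- as.matrix(x)
  apply(x, 2, function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0, length(v))
  })
}

#' One-way permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared inter-object dissimilarities among and
#' within groups (the Anderson partition computed directly from distances):
#' `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, and
#' `pseudo-F = (SS_between / df_between) / (SS_within / df_within)`.
#' Significance is assessed by unrestricted permutation of the group labels.
#' When the number of distinct label assignments is at most `max_exhaustive`
#' the permutation distribution is enumerated exactly; otherwise `n_perm`
#' Monte-Carlo draws are used and the p-value follows the add-one rule
#' `(b + 1) / (n_perm + 1)`, so it is never reported as 0.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param groups Group label per object (>= 2 groups, each non-empty).
#' @param n_perm Number of Monte-Carlo permutations (default 999).
#' @param seed RNG seed; required when Monte-Carlo sampling is used.
#' @param method `"auto"` (exhaustive when feasible), `"exhaustive"` or
#'   `"monte_carlo"`.
#' @param max_exhaustive Assignment-count ceiling for exhaustive enumeration.
#' @return An object of class `permanova`: pseudo-F, R-squared
#'   (`SS_between / SS_total`), degrees of freedom, p-value, the permutation
#'   count actually used, seed and method.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL,
                      method = c("auto", "exhaustive", "monte_carlo"),
                      max_exhaustive = 10000) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0)) {
    stop("`d` must be a symmetric matrix with zero diagonal", call. = FALSE)
  }
  groups <- as.factor(groups)
  if (length(groups) != n) stop("`groups` length must match `d`", call. = FALSE)
  if (any(table(groups) == 0L)) {
    stop("empty group level; drop unused levels first", call. = FALSE)
  }
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (n - k < 1L) stop("no residual degrees of freedom", call. = FALSE)
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)

  d2 <- d^2
  ss_total <- sum(d2[lower.tri(d2)]) / n
  gint <- as.integer(groups)
  f_of <- function(g) {
    ssw <- 0
    for (lev in seq_len(k)) {
      idx <- which(g == lev)
      if (length(idx) > 1L) {
        sub <- d2[idx, idx]
        ssw <- ssw + sum(sub[lower.tri(sub)]) / length(idx)
      }
    }
    ssb <- ss_total - ssw
    c(F = (ssb / (k - 1)) / (ssw / (n - k)), ssb = ssb, ssw = ssw)
  }
  obs <- f_of(gint)

  n_assign <- exp(lfactorial(n) - sum(lfactorial(table(groups))))
  use_exhaustive <- method == "exhaustive" ||
    (method == "auto" && n_assign <= max_exhaustive + 0.5)
  if (method == "exhaustive" && n_assign > max_exhaustive + 0.5) {
    stop("exhaustive enumeration infeasible: ", round(n_assign),
         " assignments", call. = FALSE)
  }

  if (use_exhaustive) {
    perms <- multiset_permutations(gint)
    fs <- vapply(perms, function(g) f_of(g)[1], numeric(1))
    p <- mean(fs >= obs[1] - 1e-12)
    n_used <- length(perms)
    meth <- "exhaustive"
    seed_used <- NA_integer_
  } else {
    if (is.null(seed)) {
      stop("`seed` is required for Monte-Carlo permutation", call. = FALSE)
    }
    fs <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      f_of(sample(gint))[1]
    }, numeric(1)))
    p <- (sum(fs >= obs[1] - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
    meth <- "monte_carlo"
    seed_used <- as.integer(seed)
  }

  structure(
    list(pseudo_F = unname(obs[1]), r_squared = unname(obs[2] / ss_total),
         df_between = k - 1L, df_within = n - k,
         ss_between = unname(obs[2]), ss_within = unname(obs[3]),
         ss_total = ss_total, p_value = p, n_perm = n_used,
         seed = seed_used, method = meth, n = n, groups = levels(groups)),
    class = "permanova"
  )
}

# All distinct permutations of an integer multiset (recursive enumeration).
multiset_permutations <- function(x) {
  n <- length(x)
  res <- list()
  recurse <- function(prefix, remaining) {
    if (!length(remaining)) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in unique(remaining)) {
      i <- match(v, remaining)
      recurse(c(prefix, v), remaining[-i])
    }
  }
  recurse(integer(0), sort(x))
  res
}

#' @export
print.permanova <- function(x, ...) {
  cat("Permutational multivariate analysis of variance (one-way)\n")
  cat(sprintf("  %d objects in %d groups; %s permutation (%d)\n",
              x$n, x$df_between + 1L,
              if (x$method == "exhaustive") "exhaustive" else "Monte-Carlo",
              x$n_perm))
  tab <- data.frame(
    Df = c(x$df_between, x$df_within, x$df_between + x$df_within),
    SumOfSqs = c(x$ss_between, x$ss_within, x$ss_total),
    R2 = c(x$r_squared, 1 - x$r_squared, 1),
    F = c(x$pseudo_F, NA, NA),
    `Pr(>F)` = c(x$p_value, NA, NA),
    row.names = c("groups", "residual", "total"),
    check.names = FALSE
  )
  print(format(tab, digits = 4), ...)
  invisible(x)
}

#' Write a PERMANOVA result to CSV
#' @param x A [permanova()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_permanova_csv <- function(x, path) {
  stopifnot(inherits(x, "permanova"))
  df <- data.frame(pseudo_F = x$pseudo_F, df_between = x$df_between,
                   df_within = x$df_within, r_squared = x$r_squared,
                   p_value = x$p_value, n_perm = x$n_perm,
                   seed = x$seed, method = x$method)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
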