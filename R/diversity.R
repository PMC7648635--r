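#' Mixed-type Gower distance matrix among species
#'
#' Gower's coefficient over the trait schema: quantitative components are
#' absolute differences scaled by the trait's range over the species pool in
#' `traits` (so ranges are pool-specific — pass the per-site trait subset to
#' obtain site-level ranges); binary and categorical components are simple
#' mismatches (0/1). The distance is the weighted mean of the available
#' components, with pairwise deletion of missing traits and weight
#' renormalisation. Computation is delegated to [cluster::daisy()], which
#' implements exactly these conventions; this wrapper adds schema handling
#' and validation.
#'
#' @param traits A [trait_table()] with at least 2 species.
#' @param weights Optional nonnegative per-trait weights (named or in schema
#'   order); default equal weights.
#' @return Symmetric `species x species` matrix with entries in `[0, 1]`.
#' @export
gower_matrix <- function(traits, weights = NULL) {
  stopifnot(inherits(traits, "trait_table"))
  schema <- trait_schema(traits)
  if (nrow(traits) < 2L) stop("need at least 2 species", call. = FALSE)
  w <- rep(1, length(schema))
  names(w) <- names(schema)
  if (!is.null(weights)) {
    if (!is.null(names(weights))) {
      unknown <- setdiff(names(weights), names(schema))
      if (length(unknown)) stop("unknown trait in weights: ", unknown[1],
                                call. = FALSE)
      w[names(weights)] <- weights
    } else {
      if (length(weights) != length(schema)) {
        stop("`weights` must have one entry per trait", call. = FALSE)
      }
      w[] <- weights
    }
    if (any(w < 0) || all(w == 0)) {
      stop("weights must be nonnegative and not all zero", call. = FALSE)
    }
  }
  df <- as.data.frame(traits[names(schema)])
  for (nm in names(schema)) {
    if (schema[[nm]]$kind == "binary") {
      df[[nm]] <- factor(ifelse(traits[[nm]], "yes", "no"),
                         levels = c("no", "yes"))
    }
  }
  rownames(df) <- traits$species
  d <- as.matrix(cluster::daisy(df, metric = "gower", weights = w))
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, ]
    stop("species pair with no shared non-missing trait: ",
         rownames(d)[bad[1]], " / ", colnames(d)[bad[2]], call. = FALSE)
  }
  diag(d) <- 0
  pmin(pmax(d, 0), 1)
}

#' Mean pairwise distance of a species assemblage
#'
#' The mean of the dissimilarities over all unordered species pairs present:
#' the estimator used for both functional diversity (Gower trait distances)
#' and phylogenetic diversity (patristic distances). Undefined (NA) for
#' fewer than two species.
#'
#' @param d Symmetric labelled distance matrix.
#' @param present Labels of the species present.
#' @return Mean pairwise distance, or `NA` when `length(present) < 2`.
#' @export
mpd <- function(d, present) {
  d <- as.matrix(d)
  present <- as.character(present)
  missing_sp <- setdiff(present, rownames(d))
  if (length(missing_sp)) {
    stop("label(s) not in distance matrix: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  if (length(present) < 2L) return(NA_real_)
  sub <- d[present, present]
  mean(sub[lower.tri(sub)])
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via [ape::nj()]): iteratively join the
#' pair minimising the Q-criterion, estimate the two branch lengths, reduce
#' the matrix, and return the unrooted tree over all labels. Negative
#' branch-length estimates, which arise when the input is not additive, are
#' clamped to zero with the deficit transferred to the sister branch so that
#' path lengths through the node are preserved as far as possible.
#'
#' @param d Symmetric labelled distance matrix over at least 3 taxa.
#' @return An unrooted `phylo` tree with nonnegative branch lengths.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 labels", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0) || any(d < 0)) {
    stop("`d` must be symmetric, nonnegative, with zero diagonal",
         call. = FALSE)
  }
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tree)
}

# Set negative edge lengths to 0, moving the deficit onto a sister edge.
clamp_negative_edges <- function(tree) {
  el <- tree$edge.length
  if (is.null(el) || all(el >= 0)) return(tree)
  neg <- which(el < 0)
  message(length(neg), " negative NJ branch length(s) clamped to 0")
  for (e in neg) {
    deficit <- el[e]
    el[e] <- 0
    parent <- tree$edge[e, 1]
    sisters <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sisters)) {
      el[sisters[1]] <- max(0, el[sisters[1]] + deficit)
    }
  }
  tree$edge.length <- el
  tree
}

#' Patristic (leaf-to-leaf path length) distances of a tree
#'
#' Sum of branch lengths along the unique path between every pair of leaves.
#' A tree without branch lengths falls back to nodal distances (every edge
#' counted as length 1), with a message.
#'
#' @param tree A `phylo` tree.
#' @return Symmetric matrix labelled by tip.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    message("tree has no branch lengths; using nodal (edge-count) distances")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length", call. = FALSE)
  }
  stats::cophenetic(tree)
}

#' Per-unit functional and phylogenetic diversity
#'
#' For every sampling unit, the mean pairwise Gower trait distance (FD) and
#' mean pairwise patristic distance (PD) among the species present at the
#' chosen survey. Units with fewer than two (matched) species score `NA`.
#' Species absent from the phylogenetic matrix may be mapped to a congeneric
#' stand-in through an explicit `alias` map; unmapped species are dropped
#' from PD with a warning, never matched silently.
#'
#' @param series A [survey_series()].
#' @param trait_d Species Gower matrix (see [gower_matrix()]).
#' @param phylo_d Species patristic matrix (see [patristic_distances()]).
#' @param survey Survey label; default the first survey.
#' @param alias Optional named character vector mapping series species to
#'   tree labels.
#' @return Data frame with columns `unit`, `n_species`, `fd`, `pd`.
#' @export
diversity_scores <- function(series, trait_d, phylo_d, survey = NULL,
                             alias = NULL) {
  stopifnot(inherits(series, "survey_series"))
  survey <- survey %||% series$surveys[1]
  k <- match(as.character(survey), series$surveys)
  if (is.na(k)) stop("unknown survey label '", survey, "'", call. = FALSE)
  trait_d <- as.matrix(trait_d)
  phylo_d <- as.matrix(phylo_d)
  phylo_name <- function(sp) {
    out <- ifelse(sp %in% rownames(phylo_d), sp, NA_character_)
    if (!is.null(alias)) {
      idx <- is.na(out) & sp %in% names(alias)
      out[idx] <- unname(alias[sp[idx]])
      out[!is.na(out) & !out %in% rownames(phylo_d)] <- NA
    }
    out
  }
  warned <- FALSE
  rows <- lapply(seq_along(series$units), function(u) {
    sp <- series$species[series$occupancy[u, , k]]
    sp_tr <- intersect(sp, rownames(trait_d))
    ph <- phylo_name(sp)
    dropped <- sum(is.na(ph))
    if (dropped > 0 && !warned) {
      warned <<- TRUE
      warning("species without phylogenetic match dropped from PD ",
              "(supply `alias` to map congeners)", call. = FALSE)
    }
    ph <- ph[!is.na(ph)]
    data.frame(unit = series$units[u], n_species = length(sp),
               fd = mpd(trait_d, sp_tr), pd = mpd(phylo_d, unique(ph)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation between FD and PD across units
#'
#' Rank correlation (mid-ranks for ties) between the per-unit functional and
#' phylogenetic diversity scores of one site. Units lacking either score are
#' dropped with a warning. The p-value is exact for n <= 9 without ties and
#' uses the t-approximation otherwise (two-sided).
#'
#' @param scores Data frame with columns `fd` and `pd`
#'   (see [diversity_scores()]), or a numeric vector of FD values.
#' @param pd Numeric PD vector when `scores` is a vector.
#' @return List with elements `rho`, `p_value`, `n`.
#' @export
fd_pd_correlation <- function(scores, pd = NULL) {
  if (is.data.frame(scores)) {
    fd <- scores$fd
    pd <- scores$pd
  } else {
    fd <- as.numeric(scores)
  }
  if (length(fd) != length(pd)) stop("fd/pd length mismatch", call. = FALSE)
  ok <- is.finite(fd) & is.finite(pd)
  if (any(!ok)) {
    warning(sum(!ok), " unit(s) without both scores dropped", call. = FALSE)
  }
  fd <- fd[ok]
  pd <- pd[ok]
  n <- length(fd)
  if (n < 3L) stop("fewer than 3 complete FD/PD pairs", call. = FALSE)
  ties <- anyDuplicated(fd) > 0 || anyDuplicated(pd) > 0
  ct <- suppressWarnings(
    stats::cor.test(fd, pd, method = "spearman", exact = n <= 9 && !ties)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Read / write species distance matrices and Newick trees
#'
#' Square CSV with species labels as header row and first column for
#' distance matrices; standard Newick (with branch lengths) for trees, via
#' ape.
#'
#' @param path File path.
#' @return `read_distance_csv`: a labelled symmetric matrix;
#'   `read_newick`: a `phylo`.
#' @export
read_distance_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8)) {
    stop("distance file is not a symmetric square matrix", call. = FALSE)
  }
  m
}

#' @rdname read_distance_csv
#' @param m Labelled symmetric matrix.
#' @export
write_distance_csv <- function(m, path) {
  utils::write.csv(as.data.frame(as.matrix(m)), path, quote = FALSE)
  invisible(path)
}

#' @rdname read_distance_csv
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ape::read.tree(path)
}

#' @rdname read_distance_csv
#' @param tree A `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
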