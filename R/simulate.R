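#' Configuration for the synthetic multi-site study generator
#'
#' Defines the survey design and occupancy dynamics of a simulated long-term
#' herb-layer monitoring study. The defaults mirror a four-site design with
#' 100 permanent 0.25 m^2 quadrats per site and eight surveys over twelve
#' years (labelled 1999, 2000, 2001, 2002, 2005, 2006, 2008, 2011), species
#' pools of ~33 per site with low between-site overlap, and first-order
#' Markov occupancy dynamics in which the per-survey probability that an
#' occupant persists may depend on its functional traits through log-odds
#' effects.
#'
#' @param n_sites Number of sites.
#' @param n_units Sampling units (quadrats) per site.
#' @param n_species Expected species-pool size per site.
#' @param survey_labels Ordered survey labels (length >= 2).
#' @param p_init Initial occupancy probability per (species, unit).
#' @param baseline_persist Per-survey probability that an occupant remains,
#'   for a species with average traits.
#' @param baseline_colonize Per-survey probability that an absentee appears.
#' @param trait_effects Named numeric vector of log-odds effects on
#'   persistence. Names are trait names (quantitative traits enter
#'   standardised, binary traits centred) or `"trait:level"` for a
#'   categorical level indicator. Alternatively a list of such vectors, one
#'   per site, to plant site-specific effects.
#' @param cover_law `c(meanlog, sdlog)` of the log-normal cover (%) drawn
#'   when a species is present; covers are capped at 100 and perturbed by
#'   +/-20% between surveys.
#' @param overlap Probability that a species also occurs in each site beyond
#'   its home site; 0.15 leaves ~60% of species confined to a single site.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 4, n_units = 100, n_species = 33,
                       survey_labels = c(1999, 2000, 2001, 2002,
                                         2005, 2006, 2008, 2011),
                       p_init = 0.15, baseline_persist = 0.7,
                       baseline_colonize = 0.03, trait_effects = NULL,
                       cover_law = c(meanlog = log(3), sdlog = 0.8),
                       overlap = 0.15, seed = 1) {
  stopifnot(n_sites >= 1, n_units >= 1, n_species >= 1,
            length(survey_labels) >= 2,
            p_init >= 0, p_init <= 1,
            baseline_persist >= 0, baseline_persist <= 1,
            baseline_colonize >= 0, baseline_colonize <= 1,
            overlap >= 0, overlap <= 1, length(cover_law) == 2)
  if (is.list(trait_effects) && length(trait_effects) != n_sites) {
    stop("per-site `trait_effects` must have one element per site",
         call. = FALSE)
  }
  structure(list(n_sites = as.integer(n_sites), n_units = as.integer(n_units),
                 n_species = as.integer(n_species),
                 survey_labels = as.character(survey_labels),
                 z_surveys = length(survey_labels),
                 p_init = p_init, baseline_persist = baseline_persist,
                 baseline_colonize = baseline_colonize,
                 trait_effects = trait_effects,
                 cover_law = stats::setNames(as.numeric(cover_law),
                                             c("meanlog", "sdlog")),
                 overlap = overlap, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic mixed-type trait table
#'
#' Draws the five default traits with realistic marginal distributions:
#' seed mass log-normal (median ~2 mg with a long right tail into the tens
#' of mg), SLA normal (mean 25, sd 8 mm^2 mg^-1) truncated above 5,
#' perennial belowground bud bank Bernoulli(0.6), vegetative mobility over
#' none/slow/fast with probabilities (0.2, 0.4, 0.4), and leaf anatomy over
#' the four water-economy types.
#'
#' @param n_species Number of species (>= 1).
#' @param seed RNG seed.
#' @param species Optional species labels.
#' @param anatomy_probs Sampling probabilities for the four leaf-anatomy
#'   levels (helomorphic, hygromorphic, mesomorphic, scleromorphic).
#' @return A [trait_table()].
#' @export
generate_traits <- function(n_species, seed = 1,
                            species = sprintf("sp_%03d", seq_len(n_species)),
                            anatomy_probs = c(0.15, 0.25, 0.4, 0.2)) {
  if (n_species < 1) stop("`n_species` must be >= 1", call. = FALSE)
  schema <- default_trait_schema()
  with_seed(seed, {
    sla <- stats::rnorm(n_species, 25, 8)
    while (any(bad <- sla <= 5)) {
      sla[bad] <- stats::rnorm(sum(bad), 25, 8)
    }
    df <- data.frame(
      species = species,
      seed_mass = stats::rlnorm(n_species, meanlog = log(2), sdlog = 1.2),
      bud_bank = stats::runif(n_species) < 0.6,
      sla = sla,
      veg_mobility = sample(schema$veg_mobility$levels, n_species,
                            replace = TRUE, prob = c(0.2, 0.4, 0.4)),
      leaf_anatomy = sample(schema$leaf_anatomy$levels, n_species,
                            replace = TRUE, prob = anatomy_probs),
      stringsAsFactors = FALSE
    )
    trait_table(df, schema)
  })
}

# Per-species persistence probability from baseline and trait effects.
persistence_probs <- function(traits, baseline, effects) {
  eta <- rep(stats::qlogis(min(max(baseline, 1e-12), 1 - 1e-12)),
             nrow(traits))
  if (!is.null(effects) && length(effects)) {
    schema <- trait_schema(traits)
    for (nm in names(effects)) {
      if (grepl(":", nm, fixed = TRUE)) {
        parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
        v <- traits[[parts[1]]]
        if (is.null(v)) stop("unknown trait effect '", nm, "'", call. = FALSE)
        ind <- as.numeric(!is.na(v) & as.character(v) == parts[2])
        eta <- eta + effects[[nm]] * (ind - mean(ind))
      } else {
        v <- traits[[nm]]
        if (is.null(v)) stop("unknown trait effect '", nm, "'", call. = FALSE)
        kind <- schema[[nm]]$kind
        z <- if (kind == "quantitative") {
          x <- as.numeric(v)
          x[is.na(x)] <- mean(x, na.rm = TRUE)
          s <- stats::sd(x)
          if (s > 0) (x - mean(x)) / s else rep(0, length(x))
        } else if (kind == "binary") {
          x <- as.numeric(v)
          x[is.na(x)] <- mean(x, na.rm = TRUE)
          x - mean(x)
        } else {
          stop("categorical effect must name a level, e.g. '", nm, ":fast'",
               call. = FALSE)
        }
        eta <- eta + effects[[nm]] * z
      }
    }
  }
  stats::plogis(eta)
}

#' Simulate one site's survey series
#'
#' First-order Markov occupancy per (species, unit): initial presence is
#' Bernoulli(`p_init`); an occupant persists to the next survey with a
#' trait-dependent probability whose log-odds are
#' `logit(baseline_persist) + sum(trait_effects * standardised trait)`, and
#' an absentee colonises with `baseline_colonize`. Cover when present is
#' log-normal per (species, unit) and perturbed by +/-20% between surveys.
#'
#' @param traits Trait table of the site's species pool.
#' @param config A [sim_config()].
#' @param site_id Site label.
#' @param seed RNG seed (default derived from the config).
#' @param effects Trait-effect vector for this site (defaults to
#'   `config$trait_effects` when that is a single vector).
#' @return A [survey_series()].
#' @export
simulate_series <- function(traits, config, site_id = "Site01",
                            seed = config$seed, effects = NULL) {
  stopifnot(inherits(traits, "trait_table"), inherits(config, "sim_config"))
  if (is.null(effects) && !is.list(config$trait_effects)) {
    effects <- config$trait_effects
  }
  n_sp <- nrow(traits)
  n_u <- config$n_units
  Z <- config$z_surveys
  p_persist <- persistence_probs(traits, config$baseline_persist, effects)
  with_seed(seed, {
    occ <- array(FALSE, dim = c(n_u, n_sp, Z))
    occ[, , 1] <- stats::runif(n_u * n_sp) < config$p_init
    for (z in 2:Z) {
      prev <- occ[, , z - 1]
      p <- matrix(rep(p_persist, each = n_u), nrow = n_u)
      draw <- matrix(stats::runif(n_u * n_sp), nrow = n_u)
      occ[, , z] <- ifelse(prev, draw < p, draw < config$baseline_colonize)
    }
    base_cover <- matrix(
      pmin(100, stats::rlnorm(n_u * n_sp, config$cover_law["meanlog"],
                              config$cover_law["sdlog"])),
      nrow = n_u
    )
    cover <- array(0, dim = c(n_u, n_sp, Z))
    for (z in seq_len(Z)) {
      jitter <- matrix(stats::runif(n_u * n_sp, 0.8, 1.2), nrow = n_u)
      cover[, , z] <- ifelse(occ[, , z],
                             pmin(100, pmax(0.1, base_cover * jitter)), 0)
    }
    survey_series(site_id, config$survey_labels,
                  sprintf("q%03d", seq_len(n_u)), traits$species,
                  cover, occ)
  })
}

#' Generate a random species tree
#'
#' Yule (pure-birth) topology via [ape::rphylo()] with independent
#' exponential branch lengths, unrooted; the stand-in for an externally
#' supplied phylogeny in fully synthetic runs.
#'
#' @param species Species labels (>= 3).
#' @param seed RNG seed.
#' @return An unrooted `phylo`.
#' @export
generate_tree <- function(species, seed = 1) {
  species <- as.character(species)
  if (length(species) < 3L) stop("need at least 3 species", call. = FALSE)
  with_seed(seed, {
    tr <- ape::rphylo(length(species), birth = 1, death = 0)
    tr$tip.label <- species
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1)
    ape::unroot(tr)
  })
}

#' Simulate a complete multi-site study
#'
#' Draws a global species pool whose members belong to one home site and,
#' independently with probability `overlap`, to each other site (so most
#' species are site-exclusive at low overlap); generates traits for the
#' pool, one survey series per site and a species tree.
#'
#' @param config A [sim_config()].
#' @param site_names Site labels; for the default four-site design
#'   `North01, Central02, South03, South04`.
#' @return A list with elements `traits` (global pool), `series` (named list
#'   of [survey_series()]), `tree`, `pools` (named list of per-site species
#'   vectors) and `config`.
#' @export
simulate_study <- function(config = sim_config(),
                           site_names = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$n_sites
  site_names <- site_names %||% if (ns == 4) {
    c("North01", "Central02", "South03", "South04")
  } else {
    sprintf("Site%02d", seq_len(ns))
  }
  stopifnot(length(site_names) == ns)
  n_global <- max(3L, round(ns * config$n_species /
                              (1 + (ns - 1) * config$overlap)))
  traits <- generate_traits(n_global, seed = config$seed)
  membership <- with_seed(config$seed + 1L, {
    home <- sample.int(ns, n_global, replace = TRUE)
    extra <- matrix(stats::runif(n_global * ns) < config$overlap,
                    nrow = n_global)
    m <- extra
    m[cbind(seq_len(n_global), home)] <- TRUE
    m
  })
  pools <- lapply(seq_len(ns), function(i) traits$species[membership[, i]])
  names(pools) <- site_names
  schema <- trait_schema(traits)
  series <- lapply(seq_len(ns), function(i) {
    pool_traits <- trait_table(
      as.data.frame(traits[membership[, i], , drop = FALSE]), schema)
    eff <- if (is.list(config$trait_effects)) {
      config$trait_effects[[i]]
    } else {
      config$trait_effects
    }
    simulate_series(pool_traits, config, site_id = site_names[i],
                    seed = config$seed + 10L + i, effects = eff)
  })
  names(series) <- site_names
  tree <- generate_tree(traits$species, seed = config$seed + 97L)
  list(traits = traits, series = series, tree = tree, pools = pools,
       config = config)
}

#' Materialise a synthetic study on disk
#'
#' Writes one survey CSV per site, the trait CSV and the Newick tree into
#' `dir`, creating it if needed; the file set matches what
#' [run_pipeline()] reads.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory.
#' @return Named character vector of the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(traits = file.path(dir, "traits.csv"),
             tree = file.path(dir, "tree.nwk"))
  write_trait_csv(study$traits, paths[["traits"]])
  write_newick(study$tree, paths[["tree"]])
  for (nm in names(study$series)) {
    p <- file.path(dir, paste0("survey_", nm, ".csv"))
    write_survey_csv(study$series[[nm]], p)
    paths[[paste0("survey_", nm)]] <- p
  }
  paths
}
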