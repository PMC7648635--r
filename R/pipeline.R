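#' Run the full persistence analysis pipeline
#'
#' Orchestrates the analysis sequence on a multi-site study: (1) one-way
#' PERMANOVA across sites of first-survey species composition and of
#' trait-abundance composition (both on Bray-Curtis dissimilarities, the
#' trait matrix range-standardised first); (2) per-site FD-PD Spearman
#' correlation over sampling units; (3) per-site weighted residence time
#' tables; (4) per site, two conditional inference trees relating WRT to the
#' species traits (presence/absence and abundance responses). Results are
#' returned as a list and, when `out_dir` is given, written as CSV/JSON/text
#' files plus a `run.log` recording seeds and decisions. Any stage failure
#' aborts with a stage-named error and removes partial outputs.
#'
#' @param config Either a path to a YAML file or a list. Recognised fields:
#'   `simulate` (logical; use the synthetic generator), `sim` (arguments for
#'   [sim_config()]), or input paths `survey_csvs` (named by site),
#'   `trait_csv`, `tree_newick`; plus `relcov_mode`
#'   (`"presence_only"`/`"all_surveys"`), `permanova` (list: `n_perm`,
#'   `seed`), `cit` (arguments for [cit_control()]), `alias` (named list
#'   mapping species to tree tips) and `out_dir`.
#' @param out_dir Output directory (overrides `config$out_dir`); `NULL` for
#'   no file output.
#' @return Invisibly, a list with elements `permanova_species`,
#'   `permanova_traits`, `fdpd`, `wrt`, `cits`, `study`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir
  written <- character(0)
  log_lines <- character(0)
  log_msg <- function(...) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }
  emit <- function(path, writer) {
    if (is.null(out_dir)) return(invisible())
    full <- file.path(out_dir, path)
    writer(full)
    written <<- c(written, full)
    invisible()
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  study <- stage("inputs", {
    if (isTRUE(config$simulate)) {
      cfg <- do.call(sim_config, config$sim %||% list())
      log_msg("simulated study, seed ", cfg$seed)
      simulate_study(cfg)
    } else {
      if (is.null(config$survey_csvs) || is.null(config$trait_csv)) {
        stop("config needs survey_csvs and trait_csv (or simulate: true)")
      }
      traits <- read_trait_csv(config$trait_csv)
      series <- lapply(config$survey_csvs, read_survey_csv)
      names(series) <- names(config$survey_csvs) %||%
        vapply(series, function(s) s$site, "")
      tree <- if (!is.null(config$tree_newick)) {
        read_newick(config$tree_newick)
      }
      log_msg("loaded ", length(series), " site series, ",
              nrow(traits), " species traits")
      list(traits = traits, series = series, tree = tree,
           pools = lapply(series, `[[`, "species"))
    }
  })

  relcov_mode <- config$relcov_mode %||% "presence_only"
  perm_n <- config$permanova$n_perm %||% 999
  perm_seed <- config$permanova$seed %||% 1
  cit_ctrl <- do.call(cit_control, config$cit %||% list())
  alias <- unlist(config$alias) %||% NULL
  schema <- trait_schema(study$traits)
  sites <- names(study$series)

  perm <- stage("permanova", {
    sp_all <- sort(unique(unlist(lapply(study$series, `[[`, "species"))))
    comp <- do.call(rbind, lapply(sites, function(nm) {
      m <- first_survey_abundance(study$series[[nm]])
      full <- matrix(0, nrow(m), length(sp_all),
                     dimnames = list(paste(nm, rownames(m), sep = ":"),
                                     sp_all))
      full[, colnames(m)] <- m
      full
    }))
    grp <- factor(rep(sites, vapply(study$series,
                                    function(s) length(s$units), 0L)))
    ps <- permanova(suppressWarnings(bray_curtis(comp)), grp,
                    n_perm = perm_n, seed = perm_seed, method = "monte_carlo")
    tam <- do.call(rbind, lapply(sites, function(nm) {
      trait_abundance_matrix(study$series[[nm]], study$traits)
    }))
    pt <- permanova(suppressWarnings(bray_curtis(range_standardise(tam))),
                    grp, n_perm = perm_n, seed = perm_seed,
                    method = "monte_carlo")
    log_msg(sprintf("PERMANOVA species: R2 = %.3f, p = %.4f (seed %d)",
                    ps$r_squared, ps$p_value, perm_seed))
    log_msg(sprintf("PERMANOVA traits:  R2 = %.3f, p = %.4f", pt$r_squared,
                    pt$p_value))
    emit("permanova_species.csv", function(p) write_permanova_csv(ps, p))
    emit("permanova_traits.csv", function(p) write_permanova_csv(pt, p))
    list(species = ps, traits = pt)
  })

  fdpd <- stage("diversity", {
    phylo_d <- if (!is.null(study$tree)) patristic_distances(study$tree)
    out <- lapply(sites, function(nm) {
      s <- study$series[[nm]]
      pool <- trait_table(
        as.data.frame(study$traits[study$traits$species %in% s$species, ,
                                   drop = FALSE]), schema)
      td <- gower_matrix(pool)
      if (is.null(phylo_d)) return(NULL)
      sc <- suppressWarnings(
        diversity_scores(s, td, phylo_d, alias = alias))
      ct <- fd_pd_correlation(sc)
      log_msg(sprintf("%s: FD-PD rho = %.3f, p = %.3f (n = %d)", nm,
                      ct$rho, ct$p_value, ct$n))
      c(ct, list(site = nm, scores = sc))
    })
    names(out) <- sites
    tab <- do.call(rbind, lapply(out, function(x) {
      if (is.null(x)) return(NULL)
      data.frame(site = x$site, rho = x$rho, p_value = x$p_value, n = x$n)
    }))
    if (!is.null(tab)) {
      emit("fd_pd_correlations.csv", function(p) {
        utils::write.csv(tab, p, row.names = FALSE, quote = FALSE)
      })
    }
    out
  })

  wrt <- stage("persistence", {
    out <- lapply(sites, function(nm) {
      tab <- wrt_table(study$series[[nm]], mode = relcov_mode)
      emit(paste0("wrt_", nm, ".csv"),
           function(p) write_wrt_csv(tab, p, rounded = FALSE))
      log_msg(nm, ": WRT table with ", nrow(tab), " (species, unit) records")
      tab
    })
    names(out) <- sites
    out
  })

  cits <- stage("citree", {
    out <- list()
    for (nm in sites) {
      obs <- merge(wrt[[nm]], as.data.frame(study$traits), by = "species")
      for (resp in c("wrt_pa", "wrt_abu")) {
        fml <- stats::as.formula(paste(
          resp, "~", paste(names(schema), collapse = " + ")))
        fit <- conditional_tree(fml, obs, control = cit_ctrl)
        key <- paste(nm, sub("wrt_", "", resp), sep = "_")
        out[[key]] <- fit
        emit(paste0("cit_", key, ".json"),
             function(p) cit_to_json(fit, p))
        emit(paste0("cit_", key, ".txt"),
             function(p) writeLines(render_tree(fit), p))
        root <- summary(fit)$root_trait
        log_msg(nm, " (", resp, "): root split = ",
                if (is.na(root)) "<none>" else root)
      }
    }
    out
  })

  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(list(permanova_species = perm$species,
                 permanova_traits = perm$traits,
                 fdpd = fdpd, wrt = wrt, cits = cits, study = study,
                 log = log_lines))
}
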