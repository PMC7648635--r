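#' Repeated-survey community data for one site
#'
#' A `survey_series` holds the occupancy (presence/absence) and percent cover
#' of every species in every permanent sampling unit of one site, across an
#' ordered sequence of surveys. Consecutiveness of occurrences is defined by
#' adjacency in the survey sequence, not by calendar spacing, so irregular
#' revisit intervals are treated as successive observations.
#'
#' @param site Site label (length-1 character).
#' @param surveys Ordered survey labels (length `Z >= 2`). If all labels are
#'   numeric (e.g. years) they must be strictly increasing.
#' @param units Sampling-unit labels.
#' @param species Species labels.
#' @param cover Numeric array of dimension `units x species x surveys`,
#'   percent cover in `[0, 100]`.
#' @param occupancy Optional logical array of the same dimension. When `NULL`
#'   (the default dialect) occupancy is derived as `cover > 0`. Supplying it
#'   explicitly permits presence with zero recorded cover (trace occurrences)
#'   but never absence with positive cover.
#'
#' @return An object of class `survey_series`: a list with elements `site`,
#'   `surveys`, `units`, `species`, `cover`, `occupancy`.
#' @export
survey_series <- function(site, surveys, units, species, cover,
                          occupancy = NULL) {
  site <- as.character(site)
  surveys <- as.character(surveys)
  units <- as.character(units)
  species <- as.character(species)
  if (length(site) != 1L || is.na(site) || !nzchar(site)) {
    stop("`site` must be a single non-empty label", call. = FALSE)
  }
  if (length(surveys) < 2L) stop("at least 2 surveys are required (Z >= 2)", call. = FALSE)
  for (ax in list(surveys = surveys, units = units, species = species)) {
    if (anyNA(ax) || any(!nzchar(ax))) {
      stop("axis labels must be non-empty and non-missing", call. = FALSE)
    }
  }
  if (anyDuplicated(surveys)) stop("duplicated survey labels", call. = FALSE)
  if (anyDuplicated(units)) stop("duplicated unit labels", call. = FALSE)
  if (anyDuplicated(species)) stop("duplicated species labels", call. = FALSE)
  num <- suppressWarnings(as.numeric(surveys))
  if (!anyNA(num) && any(diff(num) <= 0)) {
    stop("numeric survey labels must be strictly increasing", call. = FALSE)
  }
  dims <- c(length(units), length(species), length(surveys))
  cover <- array(as.numeric(cover), dim = dims,
                 dimnames = list(units, species, surveys))
  if (anyNA(cover) || any(!is.finite(cover))) {
    stop("cover values must be finite and non-missing", call. = FALSE)
  }
  if (any(cover < 0) || any(cover > 100)) {
    stop("cover values must lie in [0, 100]", call. = FALSE)
  }
  if (is.null(occupancy)) {
    occupancy <- cover > 0
  } else {
    occupancy <- array(as.logical(occupancy), dim = dims,
                       dimnames = list(units, species, surveys))
    if (anyNA(occupancy)) stop("occupancy must not contain NA", call. = FALSE)
    if (any(cover > 0 & !occupancy)) {
      stop("positive cover recorded for a cell marked absent", call. = FALSE)
    }
  }
  structure(
    list(site = site, surveys = surveys, units = units, species = species,
         cover = cover, occupancy = occupancy),
    class = "survey_series"
  )
}

#' @export
print.survey_series <- function(x, ...) {
  cat("Survey series for site '", x$site, "'\n", sep = "")
  cat("  ", length(x$units), " units x ", length(x$species), " species x ",
      length(x$surveys), " surveys (", x$surveys[1], "-",
      x$surveys[length(x$surveys)], ")\n", sep = "")
  cat("  occupied cells:", sum(x$occupancy), "\n")
  invisible(x)
}

n_surveys <- function(series) length(series$surveys)

#' Read a long-format survey CSV
#'
#' The canonical interchange format is a long CSV with columns
#' `site, unit, survey, species, cover` (header row, UTF-8). Rows absent from
#' the file denote absence (zero cover). An optional `occupancy` column
#' (0/1) supports the dialect in which trace occurrences are recorded as
#' present with zero cover; without it, occupancy is derived as `cover > 0`.
#'
#' @param path Path to the CSV file.
#' @param site Optional site filter; required when the file holds several
#'   sites.
#' @return A [survey_series()].
#' @export
read_survey_csv <- function(path, site = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("site", "unit", "survey", "species", "cover")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_occ <- "occupancy" %in% names(df)
  if (nrow(df) == 0L) stop("empty survey file: ", path, call. = FALSE)
  blank <- !nzchar(trimws(df$site)) | !nzchar(trimws(df$unit)) |
    !nzchar(trimws(df$survey)) | !nzchar(trimws(df$species))
  if (any(blank)) {
    stop("parse error: blank site/unit/survey/species on data line ",
         which(blank)[1], call. = FALSE)
  }
  if (!is.null(site)) {
    df <- df[df$site == as.character(site), , drop = FALSE]
    if (nrow(df) == 0L) stop("no rows for site '", site, "'", call. = FALSE)
  } else if (length(unique(df$site)) > 1L) {
    stop("file holds multiple sites (", paste(unique(df$site), collapse = ", "),
         "); supply `site`", call. = FALSE)
  }
  cov <- suppressWarnings(as.numeric(df$cover))
  if (anyNA(cov)) {
    stop("parse error: non-numeric cover on data line ", which(is.na(cov))[1],
         call. = FALSE)
  }
  if (any(cov < 0 | cov > 100)) {
    stop("cover outside [0, 100] on data line ",
         which(cov < 0 | cov > 100)[1], call. = FALSE)
  }
  key <- paste(df$unit, df$species, df$survey, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicated cell (unit=", d$unit, ", species=", d$species,
         ", survey=", d$survey, ")", call. = FALSE)
  }
  surveys <- unique(df$survey)
  nums <- suppressWarnings(as.numeric(surveys))
  surveys <- if (!anyNA(nums)) surveys[order(nums)] else sort(surveys)
  units <- sort(unique(df$unit))
  species <- sort(unique(df$species))
  dims <- c(length(units), length(species), length(surveys))
  cover <- array(0, dim = dims, dimnames = list(units, species, surveys))
  idx <- cbind(match(df$unit, units), match(df$species, species),
               match(df$survey, surveys))
  cover[idx] <- cov
  occupancy <- NULL
  if (has_occ) {
    occ_raw <- suppressWarnings(as.numeric(df$occupancy))
    if (anyNA(occ_raw) || !all(occ_raw %in% c(0, 1))) {
      stop("parse error: occupancy column must be 0/1", call. = FALSE)
    }
    occupancy <- array(FALSE, dim = dims,
                       dimnames = list(units, species, surveys))
    occupancy[idx] <- occ_raw == 1
  }
  survey_series(df$site[1], surveys, units, species, cover, occupancy)
}

#' Write a survey series to long-format CSV
#'
#' Only occupied cells are written; absence is implicit. When the series holds
#' trace occurrences (present with zero cover) an `occupancy` column is
#' included so that [read_survey_csv()] round-trips the data exactly.
#'
#' @param series A [survey_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(series, path) {
  stopifnot(inherits(series, "survey_series"))
  idx <- which(series$occupancy, arr.ind = TRUE)
  df <- data.frame(
    site = series$site,
    unit = series$units[idx[, 1]],
    survey = series$surveys[idx[, 3]],
    species = series$species[idx[, 2]],
    # full double precision so that read-back is bit-exact
    cover = sprintf("%.17g", series$cover[idx]),
    stringsAsFactors = FALSE
  )
  if (any(series$cover[idx] == 0)) df$occupancy <- 1L
  df <- df[order(df$unit, df$species, df$survey), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cover at the first survey
#'
#' Slice of the cover array at the earliest survey, as fed to the
#' between-site compositional PERMANOVA (the monitoring baseline).
#'
#' @param series A [survey_series()].
#' @return A `units x species` numeric matrix.
#' @export
first_survey_abundance <- function(series) {
  stopifnot(inherits(series, "survey_series"))
  m <- series$cover[, , 1L, drop = FALSE]
  matrix(m, nrow = length(series$units),
         dimnames = list(series$units, series$species))
}
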