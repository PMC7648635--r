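#' Trait schema for mixed-type functional traits
#'
#' A trait schema declares, for each trait, its name, measurement kind
#' (`"quantitative"`, `"binary"` or `"categorical"`), unit text and — for
#' categorical traits — the enumerated level set.
#'
#' `default_trait_schema()` returns the five-trait set used throughout the
#' package: seed mass (mg), perennial belowground bud bank (binary), specific
#' leaf area (SLA, mm^2 mg^-1), vegetative mobility (rate of clonal lateral
#' spread: none/slow/fast) and leaf anatomy (water-economy type: helomorphic,
#' hygromorphic, mesomorphic, scleromorphic).
#'
#' @return A named list of trait descriptors, each a list with elements
#'   `name`, `kind`, `unit` and (categorical only) `levels`.
#' @export
default_trait_schema <- function() {
  list(
    seed_mass = list(name = "seed_mass", kind = "quantitative", unit = "mg"),
    bud_bank = list(name = "bud_bank", kind = "binary", unit = ""),
    sla = list(name = "sla", kind = "quantitative", unit = "mm2/mg"),
    veg_mobility = list(name = "veg_mobility", kind = "categorical", unit = "",
                        levels = c("none", "slow", "fast")),
    leaf_anatomy = list(name = "leaf_anatomy", kind = "categorical", unit = "",
                        levels = c("helomorphic", "hygromorphic",
                                   "mesomorphic", "scleromorphic"))
  )
}

validate_schema <- function(schema) {
  stopifnot(is.list(schema), length(schema) >= 1L)
  for (tr in schema) {
    if (!all(c("name", "kind") %in% names(tr)) ||
        !tr$kind %in% c("quantitative", "binary", "categorical")) {
      stop("each trait descriptor needs a name and a kind in ",
           "{quantitative, binary, categorical}", call. = FALSE)
    }
    if (tr$kind == "categorical" &&
        (is.null(tr$levels) || length(tr$levels) < 2L)) {
      stop("categorical trait '", tr$name, "' needs >= 2 declared levels",
           call. = FALSE)
    }
  }
  names(schema) <- vapply(schema, `[[`, "", "name")
  schema
}

#' Species-by-trait table with declared trait kinds
#'
#' @param df Data frame with a `species` column plus one column per trait in
#'   `schema`. Quantitative traits are numeric (finite or `NA`), binary traits
#'   logical/0-1, categorical traits drawn from the declared level set.
#' @param schema A trait schema (see [default_trait_schema()]).
#' @return A `trait_table`: a data frame with the schema attached as
#'   attribute `"schema"`.
#' @export
trait_table <- function(df, schema = default_trait_schema()) {
  schema <- validate_schema(schema)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) {
    stop("trait table must have a 'species' column", call. = FALSE)
  }
  sp <- as.character(df$species)
  if (anyNA(sp) || any(!nzchar(sp))) stop("blank species label", call. = FALSE)
  if (anyDuplicated(sp)) stop("duplicated species label", call. = FALSE)
  missing_tr <- setdiff(names(schema), names(df))
  if (length(missing_tr)) {
    stop("missing trait column(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  for (tr in schema) {
    v <- df[[tr$name]]
    if (tr$kind == "quantitative") {
      v <- as.numeric(v)
      if (any(!is.finite(v) & !is.na(v))) {
        stop("non-finite value in quantitative trait '", tr$name, "'",
             call. = FALSE)
      }
    } else if (tr$kind == "binary") {
      v <- parse_binary(v, tr$name)
    } else {
      v <- as.character(v)
      bad <- !is.na(v) & !v %in% tr$levels
      if (any(bad)) {
        stop("value '", v[bad][1], "' of trait '", tr$name,
             "' outside declared levels {",
             paste(tr$levels, collapse = ", "), "}", call. = FALSE)
      }
      v <- factor(v, levels = tr$levels)
    }
    out[[tr$name]] <- v
  }
  structure(out, schema = schema, class = c("trait_table", "data.frame"))
}

parse_binary <- function(v, name) {
  if (is.logical(v)) return(v)
  s <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[s %in% c("0", "false", "f", "no", "n")] <- FALSE
  bad <- !is.na(s) & nzchar(s) & is.na(out)
  if (any(bad)) {
    stop("unparseable binary value '", v[bad][1], "' in trait '", name, "'",
         call. = FALSE)
  }
  as.logical(out)
}

trait_schema <- function(traits) attr(traits, "schema")

#' Read a wide species-by-trait CSV
#'
#' One row per species, one column per trait; the schema declares kinds and
#' units. Unparseable quantitative entries become missing with a warning.
#'
#' @inheritParams trait_table
#' @param path Path to the CSV file.
#' @return A [trait_table()].
#' @export
read_trait_csv <- function(path, schema = default_trait_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- validate_schema(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"species" %in% names(df)) {
    stop("schema error: trait file lacks a 'species' column", call. = FALSE)
  }
  for (tr in schema) {
    if (!tr$name %in% names(df)) {
      stop("schema error: trait column '", tr$name, "' missing", call. = FALSE)
    }
    if (tr$kind == "quantitative") {
      raw <- trimws(df[[tr$name]])
      v <- suppressWarnings(as.numeric(raw))
      bad <- is.na(v) & !toupper(raw) %in% c("NA", "NAN")
      if (any(bad)) {
        warning(sum(bad), " unparseable value(s) in quantitative trait '",
                tr$name, "' set to missing", call. = FALSE)
      }
      df[[tr$name]] <- v
    } else {
      df[[tr$name]][!nzchar(trimws(df[[tr$name]]))] <- NA
    }
  }
  trait_table(df, schema)
}

#' Write a trait table to CSV
#' @param traits A [trait_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(traits, path) {
  stopifnot(inherits(traits, "trait_table"))
  df <- as.data.frame(lapply(traits, function(v) {
    if (is.logical(v)) as.integer(v) else as.character(v)
  }), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
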