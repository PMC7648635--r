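#' Count runs of consecutive presences
#'
#' The weighted residence time index summarises a species' occupancy pattern
#' in one sampling unit through `P`, the number of surveys with presence, and
#' `T`, the number of maximal blocks of consecutive presences (a species seen
#' at surveys 1-2 and again at 5 has `P = 3`, `T = 2`). An all-absent pattern
#' has `T = 0`.
#'
#' @param pattern Ordered logical (or 0/1) presence sequence over surveys.
#' @return Integer run count.
#' @export
#' @examples
#' presence_runs(c(1, 0, 1, 0, 1, 0, 1, 0)) # 4
#' presence_runs(rep(1, 8))                 # 1
presence_runs <- function(pattern) {
  p <- as_presence(pattern)
  sum(p & !c(FALSE, p[-length(p)]))
}

#' Weighted residence time (presence/absence form)
#'
#' `WRT = 100 * (P / T) / Z`, where `P` is the number of surveys at which the
#' species was present in the unit, `T` the number of maximal runs of
#' consecutive presences, and `Z` the total number of surveys. The index is
#' the mean residence episode length expressed as a percentage of the series:
#' a species present throughout scores 100; a species flickering in and out
#' every survey (`P = T`) scores `100 / Z`; an all-absent pattern scores 0 by
#' convention (the ratio `0/0` is undefined).
#'
#' @inheritParams presence_runs
#' @return Percent in `[0, 100]`.
#' @export
#' @examples
#' wrt_pa(c(1, 0, 1, 0, 1, 0, 1, 0)) # 12.5
#' wrt_pa(c(1, 1, 1, 1, 1, 1, 1, 0)) # 87.5
wrt_pa <- function(pattern) {
  p <- as_presence(pattern)
  P <- sum(p)
  T_runs <- presence_runs(p)
  if (T_runs == 0L) return(0)
  100 * (P / T_runs) / length(p)
}

#' Mean relative cover of a focal species in one unit
#'
#' The per-survey share of the focal species in the summed cover of all
#' species in the unit, averaged over time. Mode `"presence_only"` (default)
#' averages over the surveys at which the focal species was present, so that
#' absence — already encoded by the presence/absence index — is not penalised
#' twice; `"all_surveys"` averages over all `Z` surveys with absences
#' contributing 0.
#'
#' @param covers Per-survey cover of the focal species.
#' @param totals Per-survey summed cover of all species in the unit
#'   (elementwise `>= covers`).
#' @param mode `"presence_only"` or `"all_surveys"`.
#' @param present Optional logical presence vector; defaults to `covers > 0`
#'   (supply it when trace occurrences carry zero cover).
#' @return Proportion in `[0, 1]`; 0 for a never-present species.
#' @export
rel_cover <- function(covers, totals, mode = c("presence_only", "all_surveys"),
                      present = NULL) {
  mode <- match.arg(mode)
  covers <- as.numeric(covers)
  totals <- as.numeric(totals)
  if (length(covers) == 0L || length(covers) != length(totals)) {
    stop("`covers` and `totals` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(covers < 0) || any(totals < covers)) {
    stop("need totals >= covers >= 0 elementwise", call. = FALSE)
  }
  if (any(totals == 0 & covers > 0)) {
    stop("inconsistent input: zero total cover where focal cover > 0",
         call. = FALSE)
  }
  present <- if (is.null(present)) covers > 0 else as_presence(present, "present")
  share <- ifelse(totals > 0, covers / totals, 0)
  if (!any(present)) return(0)
  if (mode == "presence_only") mean(share[present]) else sum(share[present]) / length(share)
}

#' Weighted residence time (abundance form)
#'
#' The presence/absence index down-weighted by the species' mean relative
#' cover: `WRT_abu = WRT_pa * Rel.cov`. Always `<= WRT_pa`, with equality at
#' full relative cover.
#'
#' @param wrt_pa_value Percent in `[0, 100]`.
#' @param relcov Proportion in `[0, 1]`.
#' @return Value in `[0, 100]`.
#' @export
wrt_abu <- function(wrt_pa_value, relcov) {
  if (!is_number(wrt_pa_value) || wrt_pa_value < 0 || wrt_pa_value > 100) {
    stop("`wrt_pa_value` must be a single value in [0, 100]", call. = FALSE)
  }
  if (!is_number(relcov) || relcov < 0 || relcov > 1) {
    stop("`relcov` must be a single value in [0, 1]", call. = FALSE)
  }
  wrt_pa_value * relcov
}

#' Persistence table for a survey series
#'
#' Computes, for every (species, unit) combination with at least one
#' presence, the components of the weighted residence time index: `P`, `T`,
#' `Z`, `wrt_pa`, the mean relative cover `relcov` and `wrt_abu`.
#'
#' @param series A [survey_series()].
#' @param mode Relative-cover averaging mode, see [rel_cover()].
#' @return A data frame of class `wrt_table` with columns `site`, `unit`,
#'   `species`, `P`, `T`, `Z`, `wrt_pa`, `relcov`, `wrt_abu`; one row per
#'   occupied (species, unit). Values are unrounded; see [wrt_report()].
#' @export
wrt_table <- function(series, mode = c("presence_only", "all_surveys")) {
  stopifnot(inherits(series, "survey_series"))
  mode <- match.arg(mode)
  Z <- n_surveys(series)
  rows <- vector("list", length(series$units))
  for (u in seq_along(series$units)) {
    occ_u <- matrix(series$occupancy[u, , ], nrow = length(series$species))
    cov_u <- matrix(series$cover[u, , ], nrow = length(series$species))
    totals <- colSums(cov_u)
    present_sp <- which(rowSums(occ_u) > 0)
    if (!length(present_sp)) next
    recs <- lapply(present_sp, function(s) {
      patt <- occ_u[s, ]
      P <- sum(patt)
      T_runs <- presence_runs(patt)
      w <- wrt_pa(patt)
      rc <- rel_cover(cov_u[s, ], totals, mode = mode, present = patt)
      data.frame(site = series$site, unit = series$units[u],
                 species = series$species[s], P = P, T = T_runs, Z = Z,
                 wrt_pa = w, relcov = rc, wrt_abu = w * rc,
                 stringsAsFactors = FALSE)
    })
    rows[[u]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(site = character(), unit = character(),
                      species = character(), P = integer(), T = integer(),
                      Z = integer(), wrt_pa = numeric(), relcov = numeric(),
                      wrt_abu = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("wrt_table", "data.frame")
  out
}

#' Round a persistence table for reporting
#'
#' Reporting convention: indices to one decimal place (halves rounded up, as
#' in printed tables, so 31.25 reports as 31.3), relative cover to two.
#' Internal computation is always unrounded.
#'
#' @param x A [wrt_table()].
#' @param digits Decimal places for the WRT columns.
#' @return A data frame with rounded `wrt_pa`, `relcov`, `wrt_abu`.
#' @export
wrt_report <- function(x, digits = 1) {
  stopifnot(is.data.frame(x))
  half_up <- function(v, d) floor(v * 10^d + 0.5) / 10^d
  x$wrt_pa <- half_up(x$wrt_pa, digits)
  x$wrt_abu <- half_up(x$wrt_abu, digits)
  x$relcov <- half_up(x$relcov, max(2, digits))
  x
}

#' Write a persistence table to CSV
#' @param x A [wrt_table()].
#' @param path Output path.
#' @param rounded Apply the [wrt_report()] rounding convention first.
#' @return `path`, invisibly.
#' @export
write_wrt_csv <- function(x, path, rounded = FALSE) {
  if (rounded) x <- wrt_report(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
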