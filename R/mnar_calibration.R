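# MNAR calibration: per-year SGA ratio between unknown- and known-status
# groups, used to scale the observed smoking prevalence to a target prevalence
# for the unknown group. This is the pipeline's core bespoke statistic:
#   p_target = p_obs * (SGA prevalence among unknown) / (SGA prevalence among known)

#' Per-year SGA ratio between unknown- and known-status groups
#'
#' SGA prevalences are simple proportions over the year's records; records
#' with unknown gestational age cannot carry an SGA flag and are excluded from
#' both numerator and denominator (the exclusion is reported). The ratio is
#' SGA prevalence in the unknown-status group divided by SGA prevalence in the
#' known-status group.
#'
#' @param records flagged registry rows (need \code{year}, \code{smoking},
#'   \code{ga_weeks}, logical \code{sga10}; see [add_sga_flags()]).
#' @param year the cohort year to evaluate.
#' @param quiet suppress the unknown-gestational-age exclusion message.
#' @return list with \code{sga_known}, \code{sga_unknown}, \code{ratio},
#'   \code{n_known}, \code{n_unknown} (counts after the exclusion).
#' @export
sga_ratio <- function(records, year, quiet = FALSE) {
  if (is.null(records$sga10))
    stop("records carry no 'sga10' column; run add_sga_flags() first", call. = FALSE)
  d <- records[records$year == year, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("no records for year %d", year), call. = FALSE)
  n_ga_unknown <- sum(is.na(d$ga_weeks))
  if (n_ga_unknown > 0 && !quiet)
    message(sprintf("year %d: excluding %d records with unknown gestational age from SGA prevalences",
                    year, n_ga_unknown))
  d <- d[!is.na(d$ga_weeks), , drop = FALSE]
  known <- is_known(d$smoking)
  n_known <- sum(known); n_unknown <- sum(!known)
  if (n_known == 0L || n_unknown == 0L)
    stop(sprintf("year %d: %s group is empty", year,
                 if (n_known == 0L) "known-status" else "unknown-status"), call. = FALSE)
  sga_known <- mean(d$sga10[known])
  sga_unknown <- mean(d$sga10[!known])
  if (sga_known == 0)
    stop(sprintf("year %d: SGA prevalence in the known group is 0; pool adjacent years before taking the ratio",
                 year), call. = FALSE)
  ratio <- sga_unknown / sga_known
  if (ratio == 0)
    warning(sprintf("year %d: no SGA births in the unknown group; target prevalence will fall below the observed prevalence",
                    year), call. = FALSE)
  list(sga_known = sga_known, sga_unknown = sga_unknown, ratio = ratio,
       n_known = n_known, n_unknown = n_unknown)
}

#' MNAR target smoking prevalence
#'
#' Scales the observed smoking prevalence by the SGA ratio:
#' \code{p_target = min(p_obs * ratio, 0.999)}. The clamp (rather than an
#' error) keeps downstream case-weighting well defined, which requires
#' \code{p_target < 1}. Ratios below 1 are allowed and propagated with a
#' warning — the MNAR assumption is directional (smokers withhold more) but
#' the statistic is well defined either way. No rounding happens here;
#' reporting rounds to one decimal of percent.
#'
#' @param p_obs observed smoking prevalence among known-status records,
#'   a proportion in (0, 1). Vectorised.
#' @param ratio positive SGA ratio (unknown / known). Vectorised.
#' @return target prevalence, same length as the inputs.
#' @export
mnar_target <- function(p_obs, ratio) {
  if (any(!(p_obs > 0 & p_obs < 1)))
    stop("'p_obs' must lie strictly inside (0, 1)", call. = FALSE)
  if (any(!(ratio > 0)))
    stop("'ratio' must be positive", call. = FALSE)
  if (any(ratio < 1))
    warning("SGA ratio below 1: target prevalence falls below the observed prevalence",
            call. = FALSE)
  pmin(p_obs * ratio, 0.999)
}

#' Calibrate MNAR target prevalences for every year
#'
#' One row per cohort year: observed smoking prevalence among known-status
#' records (daily + occasional combined), SGA prevalences and ratio, and the
#' MNAR target prevalence. Years where the ratio cannot be formed (an empty
#' group, no SGA births among known records) are kept with an explicit
#' \code{note} carrying the skip reason.
#'
#' @param records flagged viable registry rows (see [add_sga_flags()]).
#' @return data.frame of class \code{mnar_calibration} with columns
#'   \code{year}, \code{n_known}, \code{n_unknown}, \code{p_obs},
#'   \code{sga_known}, \code{sga_unknown}, \code{ratio}, \code{p_target},
#'   \code{note}.
#' @export
calibrate_all_years <- function(records) {
  years <- sort(unique(records$year))
  rows <- lapply(years, function(y) {
    d <- records[records$year == y, , drop = FALSE]
    known <- is_known(d$smoking)
    row <- data.frame(year = y, n_known = sum(known), n_unknown = sum(!known),
                      p_obs = NA_real_, sga_known = NA_real_,
                      sga_unknown = NA_real_, ratio = NA_real_,
                      p_target = NA_real_, note = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      p_obs <- mean(is_smoker(d$smoking[known]))
      r <- sga_ratio(records, y, quiet = TRUE)
      pt <- withCallingHandlers(mnar_target(p_obs, r$ratio),
                                warning = function(w) invokeRestart("muffleWarning"))
      row$p_obs <- p_obs
      row$sga_known <- r$sga_known; row$sga_unknown <- r$sga_unknown
      row$ratio <- r$ratio; row$p_target <- pt
      if (r$ratio < 1) row$note <- "ratio < 1: target below observed"
      row
    }, error = function(e) {
      row$note <- paste("skipped:", conditionMessage(e))
      row
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mnar_calibration", "data.frame")
  out
}

#' @export
print.mnar_calibration <- function(x, ...) {
  cat("MNAR calibration (per-year SGA-ratio scaling)\n")
  d <- as.data.frame(x)
  d$p_obs <- round(100 * d$p_obs, 1)
  d$p_target <- round(100 * d$p_target, 1)
  d$ratio <- round(d$ratio, 3)
  print(d[, c("year", "n_known", "n_unknown", "p_obs", "ratio", "p_target", "note")],
        row.names = FALSE)
  invisible(x)
}
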