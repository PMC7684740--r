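# Combine observed prevalence (known group) with predicted prevalence
# (unknown group) into annual totals, compute the change against the observed
# series, and render the report artifacts.

#' Count-weighted combined prevalence
#'
#' \code{p_combined = (n_known * p_obs + n_unknown * p_unknown_pred) /
#' (n_known + n_unknown)}. Vectorised.
#'
#' @param p_obs observed prevalence among the known group, in [0, 1].
#' @param n_known known-group size (>= 0).
#' @param p_unknown_pred predicted prevalence among the unknown group.
#' @param n_unknown unknown-group size (>= 0).
#' @return combined prevalence.
#' @export
combine_prevalence <- function(p_obs, n_known, p_unknown_pred, n_unknown) {
  stopifnot(all(n_known >= 0), all(n_unknown >= 0))
  if (any(n_known + n_unknown == 0))
    stop("both group counts are zero", call. = FALSE)
  p_unknown_pred[n_unknown == 0] <- 0  # contributes nothing; avoids NA * 0
  (n_known * p_obs + n_unknown * p_unknown_pred) / (n_known + n_unknown)
}

#' Change of the combined series against the observed series
#'
#' Both a relative change in percent, \code{100 * (p_combined - p_obs) /
#' p_obs}, and an absolute change in percentage points,
#' \code{100 * (p_combined - p_obs)} — reported side by side because a
#' "percent change" of a prevalence is ambiguous between the two readings.
#'
#' @param p_combined combined prevalence.
#' @param p_obs observed prevalence; relative change is undefined (NA) where
#'   it is 0.
#' @return list with \code{change_rel} (percent) and \code{change_abs}
#'   (percentage points).
#' @export
change_vs_observed <- function(p_combined, p_obs) {
  rel <- ifelse(p_obs > 0, 100 * (p_combined - p_obs) / p_obs, NA_real_)
  if (any(p_obs == 0))
    warning("observed prevalence of 0: relative change reported as missing",
            call. = FALSE)
  list(change_rel = rel, change_abs = 100 * (p_combined - p_obs))
}

#' Build the annual prevalence series
#'
#' Joins the calibration table with the annual predictions and computes the
#' combined prevalence and its change against the observed series. Years
#' without a prediction keep the observed prevalence and carry the skip note.
#'
#' @param calibration a [calibrate_all_years()] table.
#' @param predictions a [run_prediction_pipeline()] table.
#' @return data.frame of class \code{prevalence_series} with per-year counts,
#'   observed / predicted / combined prevalences, prediction CI and changes.
#' @export
build_prevalence_series <- function(calibration, predictions) {
  m <- match(calibration$year, predictions$year)
  out <- data.frame(
    year = calibration$year,
    n_known = calibration$n_known,
    n_unknown = calibration$n_unknown,
    p_obs = calibration$p_obs,
    p_unknown_pred = predictions$p_unknown_pred[m],
    p_unknown_ci_low = predictions$p_unknown_ci_low[m],
    p_unknown_ci_high = predictions$p_unknown_ci_high[m],
    note = ifelse(is.na(m) | is.na(predictions$p_unknown_pred[m]),
                  paste0("no prediction",
                         ifelse(predictions$note[m] %in% c("", NA), "",
                                paste0(": ", predictions$note[m]))),
                  ""),
    stringsAsFactors = FALSE
  )
  have <- !is.na(out$p_unknown_pred)
  out$p_combined <- out$p_obs
  out$p_combined[have] <- combine_prevalence(out$p_obs[have], out$n_known[have],
                                             out$p_unknown_pred[have],
                                             out$n_unknown[have])
  ch <- change_vs_observed(out$p_combined, out$p_obs)
  out$change_rel <- ch$change_rel
  out$change_abs <- ch$change_abs
  class(out) <- c("prevalence_series", "data.frame")
  out
}

#' @export
print.prevalence_series <- function(x, ...) {
  cat("Observed / predicted / combined smoking prevalence\n")
  d <- as.data.frame(x)
  for (cn in c("p_obs", "p_unknown_pred", "p_combined"))
    d[[cn]] <- round(100 * d[[cn]], 1)
  d$change_rel <- round(d$change_rel, 1)
  d$change_abs <- round(d$change_abs, 2)
  print(d[, c("year", "p_obs", "p_unknown_pred", "p_combined", "change_rel",
              "change_abs", "note")], row.names = FALSE)
  invisible(x)
}

#' Render the report artifacts
#'
#' Writes full-precision CSVs of the series, calibration and predictions, a
#' prevalence-series figure (observed, predicted and combined lines with the
#' Wilson CI band on the prediction), a registry overview figure (observed
#' smoking prevalence and unknown-status share), and a run manifest (JSON:
#' configuration, seeds, package version, filter counts). The manifest carries
#' no timestamps, so a rerun from the same configuration and seed reproduces
#' every artifact byte for byte. The prediction CI band reflects
#' classification sampling error only, not model uncertainty; the manifest
#' records this.
#'
#' @param series a [build_prevalence_series()] table.
#' @param calibration a [calibrate_all_years()] table.
#' @param predictions a [run_prediction_pipeline()] table.
#' @param out_dir output directory (created if needed).
#' @param config optional [registry_config()] used for the run.
#' @param seeds optional named list/vector of seeds used.
#' @param counts optional named counts at each filtering step.
#' @return named character vector of the files written, invisibly.
#' @export
render_report <- function(series, calibration, predictions, out_dir,
                          config = NULL, seeds = NULL, counts = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(series = file.path(out_dir, "prevalence_series.csv"),
             calibration = file.path(out_dir, "calibration.csv"),
             predictions = file.path(out_dir, "annual_predictions.csv"),
             fig_series = file.path(out_dir, "prevalence_series.png"),
             fig_overview = file.path(out_dir, "registry_overview.png"),
             manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(as.data.frame(series), paths[["series"]], row.names = FALSE)
  utils::write.csv(as.data.frame(calibration), paths[["calibration"]], row.names = FALSE)
  utils::write.csv(as.data.frame(predictions), paths[["predictions"]], row.names = FALSE)

  d <- as.data.frame(series)
  have_pred <- any(!is.na(d$p_unknown_pred))
  p1 <- ggplot2::ggplot(d, ggplot2::aes(x = year))
  if (have_pred)
    p1 <- p1 +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * p_unknown_ci_low,
                                        ymax = 100 * p_unknown_ci_high),
                           fill = "grey80", alpha = 0.6) +
      ggplot2::geom_line(ggplot2::aes(y = 100 * p_unknown_pred,
                                      colour = "predicted (unknown group)"),
                         linetype = "dotted", linewidth = 0.8)
  p1 <- p1 +
    ggplot2::geom_line(ggplot2::aes(y = 100 * p_obs, colour = "observed (known group)"),
                       linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = 100 * p_combined, colour = "combined"),
                       linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c("observed (known group)" = "#2166ac",
                                            "predicted (unknown group)" = "grey40",
                                            "combined" = "black"), name = NULL) +
    ggplot2::labs(x = "year", y = "smoking prevalence (%)",
                  title = "Observed, predicted and combined smoking prevalence",
                  caption = "CI band: Wilson interval on the classified fraction (sampling error only)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paths[["fig_series"]], p1, width = 8, height = 5, dpi = 150)

  ov <- data.frame(year = calibration$year,
                   smoking = 100 * calibration$p_obs,
                   unknown = 100 * calibration$n_unknown /
                     (calibration$n_known + calibration$n_unknown))
  p2 <- ggplot2::ggplot(ov, ggplot2::aes(x = year)) +
    ggplot2::geom_line(ggplot2::aes(y = smoking, colour = "observed smoking"),
                       linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = unknown, colour = "unknown smoking status"),
                       linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c("observed smoking" = "#2166ac",
                                            "unknown smoking status" = "#b2182b"),
                                 name = NULL) +
    ggplot2::labs(x = "year", y = "% of births", title = "Registry overview") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(paths[["fig_overview"]], p2, width = 8, height = 5, dpi = 150)

  manifest <- list(
    package = "smokemnar",
    version = as.character(utils::packageVersion("smokemnar")),
    config = config, seeds = seeds, counts = counts,
    years = series$year,
    n_predicted_years = sum(!is.na(series$p_unknown_pred)),
    ci_note = "prediction intervals are Wilson intervals on the classified fraction; model uncertainty is not propagated"
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(paths)
}
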